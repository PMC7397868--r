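# Nonclassical RNA-binding domains (Pfam ids): folds recurrently
# recovered in crosslinking studies without a canonical RNA-binding
# surface. Editable: one id per line, '#' starts a comment.
PF01423  # LSM
PF00575  # S1 RNA-binding domain
PF00096  # zf-C2H2
PF00400  # WD40 repeat
PF00118  # TCP-1/cpn60 chaperonin family
PF00012  # HSP70
PF00085  # Thioredoxin
PF00171  # Aldehyde dehydrogenase family
PF00160  # Cyclophilin-type peptidyl-prolyl cis-trans isomerase
PF00009  # GTP_EFTU, elongation factor Tu GTP-binding domain
PF03144  # GTP_EFTU_D2, elongation factor Tu domain 2
PF01926  # MMR_HSR1, 50S ribosome-binding GTPase
PF00271  # Helicase_C
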