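# Classical RNA-binding domains (Pfam ids). Editable: one id per line,
# '#' starts a comment. Replace with your own vocabulary as needed.
PF00076  # RRM_1, RNA recognition motif
PF00013  # KH_1
PF07650  # KH_2
PF00035  # dsrm, double-stranded RNA binding
PF00098  # zf-CCHC
PF00642  # zf-CCCH
PF05383  # La domain
PF00806  # PUF repeat
PF00313  # CSD, cold-shock domain
PF00270  # DEAD box helicase
PF02170  # PAZ
PF02171  # Piwi
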