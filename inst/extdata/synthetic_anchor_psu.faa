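>psu_like_anchor synthetic stand-in anchor protein (not the natural Psu)
EGYTHHTVAVGNAAPVVVYIWIDLGIAVRFLGVVAMSETDASPCALSSTKSQPSLTPDMV
LHSRLGGGQSADGCILQSKATGNVRPAHALQKLELTDEYLVAWTSLGLTSTESYAGAHLR
SQIREVNVDQKHDLTDMKSASLPGVTDEEHLKHFFQVVPDSALQCFFGPLLLGEYSAALA
IVEVIQQETE
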