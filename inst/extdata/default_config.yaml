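# Default configuration. Any field may be omitted; missing fields keep
# the package defaults shown here.
scaffold: GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCAACTTGAAAAAGTGGCACCGAGTCGGTGC
dcnWindow: [32, 40]      # optimal distance-between-cis-nicks window, nt
dcnHardMin: 25           # DCNs of 24 nt or shorter are always rejected
pbsLen: 12               # primer binding site length (9-16 supported)
hsLen: 16                # homologous sequence length (12-22 tested)
mismatchScheme: consecutive   # none | consecutive | every3 | every5
mismatchK: 11            # number of flap-disruption mismatches
mismatchSide: auto       # auto | three_prime_flap | five_prime_flap
helperPolicy: auto       # auto | on | off
helperEsThreshold: 70    # ES length (nt) at which a Helper gRNA is added
helperMinSeparation: 25  # min distance of helper nick to flanking nicks
quantW: 10               # quantification window flank, nt
u6G: false               # prepend G to G-less spacers (U6 expression)
maxDesigns: 10
seed: 1729
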