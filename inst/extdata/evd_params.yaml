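# Constants of the expectation function
#   EF(r) = theta * exp(a) * r^(b * (n - 1))
# the expected number of random n-residue structural matches with
# superposition RMSD <= r, for a match whose residue types have abundance
# product theta.  b is the per-residue shape-degree-of-freedom exponent
# (2 points x 3 coordinates per residue, minus rigid motion: 6(n-1) in
# total), and exp(a) is a scale constant fitted on this package's synthetic
# decoy background (see the methods vignette).  Replace with your own fit
# for a different background.  b must be > 0 (EF strictly increasing in
# RMSD).
a: 5.2
b: 6.0
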