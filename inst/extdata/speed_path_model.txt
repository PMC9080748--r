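# Default seven-variable sidewinding speed model
# (size-corrected residuals; fit on their correlation matrix)
variables: frequency, wavelength, amplitude, skew, height, width50, speed
path: frequency -> speed
path: wavelength -> speed
path: amplitude -> speed
path: skew -> speed
path: width50 -> wavelength
cov: frequency ~~ amplitude
cov: frequency ~~ skew
cov: frequency ~~ height
cov: frequency ~~ width50
cov: amplitude ~~ skew
cov: amplitude ~~ height
cov: amplitude ~~ width50
cov: skew ~~ height
cov: skew ~~ width50
cov: height ~~ width50
cov: wavelength ~~ frequency
cov: wavelength ~~ amplitude
cov: wavelength ~~ skew
cov: wavelength ~~ height
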