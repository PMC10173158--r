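# Screening-level toxicity values for the ten soil metals handled by default.
# Reference doses (RfD) in mg/(kg day) by exposure pathway; oral carcinogenic
# slope factors (SF_ing) in (mg/(kg day))^-1. Values follow USEPA IRIS /
# regional screening conventions for residential soil; they are starting
# points, not site-specific toxicology, and every entry can be overridden via
# load_toxicity_profiles(). Metals without an established value omit the key:
# risk code skips those metal-pathway combinations with a warning.
As:
  RfD_ing: 3.0e-4
  RfD_inh: 3.01e-4
  RfD_derm: 1.23e-4
  SF_ing: 1.5
  carcinogen: true
Cd:
  RfD_ing: 1.0e-3
  RfD_inh: 1.0e-3
  RfD_derm: 1.0e-5
  SF_ing: 6.1
  carcinogen: true
Cr:
  RfD_ing: 3.0e-3
  RfD_inh: 2.86e-5
  RfD_derm: 6.0e-5
  SF_ing: 0.5
  carcinogen: true
Ni:
  RfD_ing: 2.0e-2
  RfD_inh: 2.06e-2
  RfD_derm: 5.4e-3
Pb:
  RfD_ing: 3.5e-3
  RfD_inh: 3.52e-3
  RfD_derm: 5.25e-4
  SF_ing: 8.5e-3
  carcinogen: true
Cu:
  RfD_ing: 4.0e-2
  RfD_inh: 4.02e-2
  RfD_derm: 1.2e-2
Zn:
  RfD_ing: 3.0e-1
  RfD_inh: 3.0e-1
  RfD_derm: 6.0e-2
Mn:
  RfD_ing: 4.6e-2
  RfD_inh: 1.43e-5
  RfD_derm: 1.84e-3
Fe:
  RfD_ing: 7.0e-1
  RfD_derm: 7.0e-1
Mg: {}
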