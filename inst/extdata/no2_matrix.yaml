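# Default NO2 risk-matrix profile.
#
# Likelihood bands score the fraction of a work shift spent at a location;
# severity bands score the indoor NO2 concentration (ug/m3) by the health
# effects associated with each exposure band. Outer bands are open at the
# internal edges, the middle band is closed on both ends, so the bands
# partition the domain with no gaps or overlaps.
name: no2_default
likelihood:
  - score: 1
    lower: 0.0
    upper: 0.25
    lower_closed: true
    upper_closed: false
    description: Unlikely
  - score: 2
    lower: 0.25
    upper: 0.75
    lower_closed: true
    upper_closed: true
    description: Likely
  - score: 3
    lower: 0.75
    upper: 1.0
    lower_closed: false
    upper_closed: true
    description: Very likely
severity:
  - score: 1
    lower: 0.0
    upper: 500.0
    lower_closed: true
    upper_closed: false
    description: Minor effect
  - score: 2
    lower: 500.0
    upper: 2000.0
    lower_closed: true
    upper_closed: true
    description: Moderate effect
  - score: 3
    lower: 2000.0
    upper: .inf
    lower_closed: false
    upper_closed: false
    description: Major effect
categories:
  - category: low
    color: green
    rf: [1, 2]
  - category: moderate
    color: yellow
    rf: [3, 4]
  - category: high
    color: bright_red
    rf: [6]
  - category: very_high
    color: deep_red
    rf: [9]
aliases:
  medium: moderate
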