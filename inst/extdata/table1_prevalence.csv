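source,endpoint,age_low,age_high,n,prevalence_pct,assumed_n
Brinjikji,disk degeneration,20,29,273,37,FALSE
Brinjikji,disk degeneration,30,39,604,52,FALSE
Brinjikji,disk degeneration,40,49,415,68,FALSE
Brinjikji,disk degeneration,50,59,311,80,FALSE
Brinjikji,disk signal loss,20,29,46,17,FALSE
Brinjikji,disk signal loss,30,39,142,33,FALSE
Brinjikji,disk signal loss,40,49,352,54,FALSE
Brinjikji,disk signal loss,50,59,73,73,FALSE
Brinjikji,disk height loss,20,29,15,24,FALSE
Brinjikji,disk height loss,30,39,163,34,FALSE
Brinjikji,disk height loss,40,49,186,45,FALSE
Brinjikji,disk height loss,50,59,208,56,FALSE
Brinjikji,disk bulge,20,29,55,30,FALSE
Brinjikji,disk bulge,30,39,101,40,FALSE
Brinjikji,disk bulge,40,49,151,50,FALSE
Brinjikji,disk bulge,50,59,123,60,FALSE
Brinjikji,disk protrusion,20,29,87,29,FALSE
Brinjikji,disk protrusion,30,39,468,31,FALSE
Brinjikji,disk protrusion,40,49,490,33,FALSE
Brinjikji,disk protrusion,50,59,363,36,FALSE
Brinjikji,annular fissure,20,29,167,19,FALSE
Brinjikji,annular fissure,30,39,350,20,FALSE
Brinjikji,annular fissure,40,49,426,22,FALSE
Brinjikji,annular fissure,50,59,53,23,FALSE
Brinjikji,facet degeneration,20,29,100,4,TRUE
Brinjikji,facet degeneration,30,39,100,9,TRUE
Brinjikji,facet degeneration,40,49,596,18,FALSE
Brinjikji,facet degeneration,50,59,53,32,FALSE
Brinjikji,spondylolisthesis,20,29,100,3,TRUE
Brinjikji,spondylolisthesis,30,39,100,5,TRUE
Brinjikji,spondylolisthesis,40,49,31,8,FALSE
Brinjikji,spondylolisthesis,50,59,53,14,FALSE
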