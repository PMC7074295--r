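method,selector,target,auc,sensitivity,specificity,plr,nlr,ppv,npv,youden
stacking,none,macrosomia,0.852,0.607,0.867,4.562,0.453,0.479,0.916,0.474
stacking,lasso,macrosomia,0.907,0.768,0.874,6.099,0.266,0.551,0.949,0.642
stacking,scad,macrosomia,0.909,0.839,0.849,5.555,0.189,0.528,0.963,0.688
stacking,mcp,macrosomia,0.907,0.786,0.863,5.748,0.258,0.537,0.952,0.649
voting,none,macrosomia,0.903,0.613,0.912,6.991,0.425,0.608,0.914,0.525
voting,lasso,macrosomia,0.891,0.542,0.959,8.885,0.809,0.664,0.902,0.481
voting,scad,macrosomia,0.932,0.845,0.836,5.143,0.185,0.681,0.533,0.681
voting,mcp,macrosomia,0.924,0.810,0.854,5.565,0.223,0.553,0.953,0.664
stacking,none,lga,0.785,0.485,0.947,9.121,0.544,0.500,0.944,0.432
stacking,lasso,lga,0.811,0.455,0.944,8.048,0.578,0.469,0.940,0.398
stacking,scad,lga,0.785,0.455,0.944,8.048,0.578,0.469,0.940,0.398
stacking,mcp,lga,0.775,0.485,0.937,7.681,0.550,0.457,0.943,0.421
voting,none,lga,0.823,0.485,0.950,9.729,0.542,0.516,0.944,0.435
voting,lasso,lga,0.811,0.515,0.940,8.614,0.516,0.486,0.946,0.455
voting,scad,lga,0.799,0.515,0.944,9.121,0.514,0.500,0.947,0.459
voting,mcp,lga,0.774,0.636,0.900,6.385,0.404,0.412,0.958,0.537
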