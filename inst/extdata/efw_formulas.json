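{
  "comment": [
    "Bank of 26 published sonographic estimated-fetal-weight (EFW) formulas.",
    "Variables in expressions: bpd, mad, fl, ac, hc -- all in CENTIMETRES",
    "(estimate_fetal_weight() converts mm inputs to cm and derives ac/hc",
    "before evaluation, except where an expression converts to mm itself).",
    "Each expression evaluates to grams. Coefficients are transcribed from",
    "the original publications and the standard secondary compilations of",
    "sonographic weight-estimation models; entries flagged in 'note' follow",
    "secondary-source transcriptions and should be re-verified against the",
    "original article before any clinical use.",
    "'family' tags the functional form: log10lin (log10-linear in biometry",
    "terms), lnlin (natural-log-linear), power (power-product/volumetric),",
    "linear (linear in biometry products)."
  ],
  "formulas": [
    {"id": 1,  "name": "Warsof 1977 (BPD, AC)",        "inputs": ["BPD", "AC"],        "family": "log10lin", "expr": "1000 * 10^(-1.599 + 0.144*bpd + 0.032*ac - 0.000111*bpd^2*ac)"},
    {"id": 2,  "name": "Campbell & Wilkin 1975 (AC)",  "inputs": ["AC"],               "family": "lnlin",    "expr": "1000 * exp(-4.564 + 0.282*ac - 0.00331*ac^2)"},
    {"id": 3,  "name": "Jordaan 1983 (AC)",            "inputs": ["AC"],               "family": "log10lin", "expr": "10^(0.6328 + 0.1881*ac - 0.0043*ac^2 + 0.0000365*ac^3)"},
    {"id": 4,  "name": "Shepard 1982 (BPD, AC)",       "inputs": ["BPD", "AC"],        "family": "log10lin", "expr": "1000 * 10^(-1.7492 + 0.166*bpd + 0.046*ac - 0.002646*ac*bpd)"},
    {"id": 5,  "name": "Hadlock 1984 (BPD, AC)",       "inputs": ["BPD", "AC"],        "family": "log10lin", "expr": "10^(1.1134 + 0.05845*ac - 0.000604*ac^2 - 0.007365*bpd^2 + 0.000595*bpd*ac + 0.1694*bpd)"},
    {"id": 6,  "name": "Hadlock 1985 I (AC, FL)",      "inputs": ["AC", "FL"],         "family": "log10lin", "expr": "10^(1.304 + 0.05281*ac + 0.1938*fl - 0.004*ac*fl)"},
    {"id": 7,  "name": "Hadlock 1985 II (BPD, AC, FL)","inputs": ["BPD", "AC", "FL"],  "family": "log10lin", "expr": "10^(1.335 - 0.0034*ac*fl + 0.0316*bpd + 0.0457*ac + 0.1623*fl)"},
    {"id": 8,  "name": "Hadlock 1985 III (HC, AC, FL)","inputs": ["HC", "AC", "FL"],   "family": "log10lin", "expr": "10^(1.326 - 0.00326*ac*fl + 0.0107*hc + 0.0438*ac + 0.158*fl)"},
    {"id": 9,  "name": "Hadlock 1985 IV (BPD, HC, AC, FL)", "inputs": ["BPD", "HC", "AC", "FL"], "family": "log10lin", "expr": "10^(1.3596 + 0.0064*hc + 0.0424*ac + 0.174*fl + 0.00061*bpd*ac - 0.00386*ac*fl)"},
    {"id": 10, "name": "Shinozuka 1987 (BPD, AC, FL)", "inputs": ["BPD", "AC", "FL"],  "family": "power",    "expr": "0.23966*ac^2*fl + 1.6230*bpd^3"},
    {"id": 11, "name": "Combs 1993 (HC, AC, FL)",      "inputs": ["HC", "AC", "FL"],   "family": "power",    "expr": "0.23718*ac^2*fl + 0.03312*hc^3"},
    {"id": 12, "name": "Ott 1986 (HC, AC, FL)",        "inputs": ["HC", "AC", "FL"],   "family": "log10lin", "expr": "1000 * 10^(-2.0661 + 0.04355*hc + 0.05394*ac - 0.0008582*hc*ac + 1.2594*(fl/ac))"},
    {"id": 13, "name": "Woo 1985 (BPD, AC, FL)",       "inputs": ["BPD", "AC", "FL"],  "family": "log10lin", "expr": "10^(1.54 + 0.15*bpd + 0.00111*ac^2 - 0.0000764*bpd*ac^2 + 0.05*fl - 0.000992*fl*ac)"},
    {"id": 14, "name": "Vintzileos 1987 (BPD, AC)",    "inputs": ["BPD", "AC"],        "family": "log10lin", "expr": "10^(1.879 + 0.084*bpd + 0.026*ac)"},
    {"id": 15, "name": "Thurnau 1983 (BPD, AC)",       "inputs": ["BPD", "AC"],        "family": "linear",   "expr": "9.337*bpd*ac - 299"},
    {"id": 16, "name": "Woo 1985 (BPD, AC)",           "inputs": ["BPD", "AC"],        "family": "log10lin", "expr": "10^(1.63 + 0.16*bpd + 0.00111*ac^2 - 0.0000859*bpd*ac^2)", "note": "secondary-source transcription"},
    {"id": 17, "name": "Weiner 1985 (HC, AC, FL)",     "inputs": ["HC", "AC", "FL"],   "family": "log10lin", "expr": "10^(1.6961 + 0.02253*hc + 0.01645*ac + 0.06439*fl)", "note": "secondary-source transcription"},
    {"id": 18, "name": "Hsieh 1987 (BPD, AC)",         "inputs": ["BPD", "AC"],        "family": "log10lin", "expr": "10^(2.1315 + 0.0056541*ac*bpd - 0.00015515*bpd*ac^2 + 0.000019782*ac^3 + 0.052594*bpd)"},
    {"id": 19, "name": "Hsieh 1990 (BPD, AC, FL)",     "inputs": ["BPD", "AC", "FL"],  "family": "log10lin", "expr": "10^(2.7193 + 0.0094962*ac*bpd - 0.1432*fl - 0.00076742*ac*bpd^2 + 0.001745*fl*bpd^2)"},
    {"id": 20, "name": "Jordaan 1983 (BPD, AC)",       "inputs": ["BPD", "AC"],        "family": "log10lin", "expr": "1000 * 10^(-1.1683 + 0.0377*ac + 0.0950*bpd - 0.0015*bpd*ac)", "note": "secondary-source transcription"},
    {"id": 21, "name": "Higginbottom 1975 (AC)",       "inputs": ["AC"],               "family": "power",    "expr": "0.0816*ac^3"},
    {"id": 22, "name": "Persson & Weldner 1986 (BPD, MAD, FL)", "inputs": ["BPD", "MAD", "FL"], "family": "power", "expr": "10^(0.972*log10(bpd*10) + 1.743*log10(mad*10) + 0.367*log10(fl*10) - 2.646)"},
    {"id": 23, "name": "Shinozuka 1996 Tokyo (BPD, AC, FL)", "inputs": ["BPD", "AC", "FL"], "family": "power", "expr": "1.07*bpd^3 + 0.30*ac^2*fl"},
    {"id": 24, "name": "Ferrero 1994 (AC, FL)",        "inputs": ["AC", "FL"],         "family": "log10lin", "expr": "10^(0.77125 + 0.13244*ac - 0.12996*fl - 0.00173588*ac^2 + 0.00309212*fl*ac + 2.18984*fl/ac)", "note": "secondary-source transcription"},
    {"id": 25, "name": "Rose & McCallum 1987 (BPD, MAD, FL)", "inputs": ["BPD", "MAD", "FL"], "family": "lnlin", "expr": "exp(0.143*(bpd + mad + fl) + 4.198)", "note": "secondary-source transcription"},
    {"id": 26, "name": "Hadlock 1984 (AC)",            "inputs": ["AC"],               "family": "lnlin",    "expr": "exp(2.695 + 0.253*ac - 0.00275*ac^2)"}
  ]
}
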