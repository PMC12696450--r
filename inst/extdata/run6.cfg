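# Example perfusion run "run6" (donor cells, media B); units as in run1.cfg
tI   = 0.08
tsed = 0.83
tF   = 4.85
Dmin = 0.067
Kp   = 0.215
Ki   = 5.16
Kd   = 7.46e-5
SI   = 26
Ssp  = 21
XI   = 1.49
XF   = 18.2
V    = 134
tlag_minus_tI = 0.000
nu   = -0.761
Yxs  = 0.311
Ypx  = 7.99
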