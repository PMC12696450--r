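# Example perfusion run "run4" (patient CAR T cells, media A); units as in run1.cfg
tI   = 2.09
tsed = 2.84
tF   = 7.00
Dmin = 0.067
Kp   = 0.215
Ki   = 5.16
Kd   = 7.46e-5
SI   = 25
Ssp  = 20
XI   = 0.62
XF   = 10.9
V    = 134
tlag_minus_tI = 0.128
nu   = -0.524
Yxs  = 0.272
Ypx  = 9.09
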