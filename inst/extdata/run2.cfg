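# Example perfusion run "run2" (donor cells, media A); units as in run1.cfg
tI   = 0.14
tsed = 1.02
tF   = 6.03
Dmin = 0.067
Kp   = 0.215
Ki   = 5.16
Kd   = 7.46e-5
SI   = 25
Ssp  = 20
XI   = 0.37
XF   = 19.0
V    = 134
tlag_minus_tI = 0.172
nu   = -0.477
Yxs  = 0.275
Ypx  = 6.25
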