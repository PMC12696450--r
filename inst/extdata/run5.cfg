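# Example perfusion run "run5" (donor cells, media A, exponential-limit
# growth: nu = 0); units as in run1.cfg
tI   = 1.92
tsed = 2.92
tF   = 6.95
Dmin = 0.067
Kp   = 0.215
Ki   = 5.16
Kd   = 7.46e-5
SI   = 25
Ssp  = 17
XI   = 1.13
XF   = 8.73
V    = 134
tlag_minus_tI = 0.000
nu   = 0
Yxs  = 0.207
Ypx  = 6.83
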