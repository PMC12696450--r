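# Example perfusion run "run3" (donor cells, media A); held-out test run,
# so no fitted kinetic block. Units as in run1.cfg
tI   = 0.11
tsed = 0.86
tF   = 6.01
Dmin = 0.067
Kp   = 0.215
Ki   = 5.16
Kd   = 7.46e-5
SI   = 25
Ssp  = 20
XI   = 1.49
XF   = 32.5
V    = 134
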