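# Example perfusion run "run1" (donor cells, media A)
# units: times [days]; S, P [mmol/L]; X [1e6 cells/mL]; D [1/day];
#        Kp [L/(mmol day)]; Ki [L/(mmol day^2)]; Kd [L/mmol]; V [mL];
#        Yxs [cells/pmol]; Ypx [pmol/cell]; tlag_minus_tI [days]; nu [-]
tI   = 0.11
tsed = 0.34
tF   = 5.05
Dmin = 0.067
Kp   = 0.215
Ki   = 5.16
Kd   = 7.46e-5
SI   = 25
Ssp  = 20
XI   = 1.49
XF   = 19.0
V    = 134
# best-fit kinetics (mu_max derived from the run endpoints)
tlag_minus_tI = 0.160
nu   = -0.922
Yxs  = 0.231
Ypx  = 7.93
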