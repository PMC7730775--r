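Coincidence analysis solution set
thresholds: con >= 1, cov >= 1; maxstep = (3, 4, 10)
outcome HI_UPTAKE=1:
  msc (3):
    SCHOOLS=2  [con 1/1 (1.00), cov 4/7 (0.57)]
    CCY=0*MC=1*SCHOOLS=1  [con 1/1 (1.00), cov 3/7 (0.43)]
    CCY=0*SBI=1*SM=0  [con 1/1 (1.00), cov 1/7 (0.14)]
  asf (1):
    SCHOOLS=2 + CCY=0*MC=1*SCHOOLS=1 <-> HI_UPTAKE=1  [con 1/1 (1.00), cov 1/1 (1.00)]
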