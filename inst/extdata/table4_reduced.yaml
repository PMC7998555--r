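# Reduced-replication version of the dense-model (r/p = 0.3) trimmed-vs-CV
# comparison grid: all 28 method columns at M = 20 replicates and B = 50
# subspaces. Full-scale settings (M = 2000, B = 250) are a matter of
# raising M and B; expect days of CPU time.
model: strong_corr
design: random
p: 1000
r: 300
n: 180
M: 20
B: 50
L: 100
trim_fraction: 0.10
K: 10
seed: 20260930
reference: CVLasso
out_dir: table4_reduced_out
methods:
  - CVLasso
  - TrLasso
  - ETrLasso(1)
  - ETrLasso(2)
  - ETrLasso(3)
  - ECVLasso(1)
  - ECVLasso(2)
  - ECVLasso(3)
  - TrELNET(0.25)
  - ETrELNET(1,0.25)
  - ETrELNET(2,0.25)
  - ETrELNET(3,0.25)
  - TrELNET(0.5)
  - ETrELNET(1,0.5)
  - ETrELNET(2,0.5)
  - ETrELNET(3,0.5)
  - TrELNET(0.75)
  - ETrELNET(1,0.75)
  - ETrELNET(2,0.75)
  - ETrELNET(3,0.75)
  - TrLARS
  - ETrLARS(1)
  - ETrLARS(2)
  - ETrLARS(3)
  - TrAlasso
  - ETrAlasso(1)
  - TrSCAD
  - ETrSCAD(1)
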