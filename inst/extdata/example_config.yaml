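# Reference setting 1: exponential patience (mean 16 h) censored by
# exponential waiting (mean 2 h), announcement probability exp(-t).
t:
  family: exponential
  mean: 16
w:
  family: exponential
  mean: 2
q:
  name: exp_decay
  rate: 1
n: 1000
seed: 7
out_dir: patsurv-run
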