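# Demo run: synthetic three-group cohort on the 19-node subcortical atlas,
# reduced permutation count so the whole pipeline finishes in well under a
# minute.  All values overridable on the command line.
seed: 7
atlas: subcortical19
modality: subcortical_volume
generator:
  group_sizes: {HC: 19, EM: 17, CM: 12}
  latent_dim: 4
  effect:
    target_group: CM
    target_regions: [1, 2, 3, 4, 5, 6]
    decorrelation: 0.9
densities: {from: 0.15, to: 0.50, by: 0.05}
ranking: absolute
n_perm: 100
nbs_threshold: 2.58
contrasts:
  - [EM, HC]
  - [CM, HC]
  - [EM, CM]
svr:
  scores: [MIDAS, attacks]
  groups: [EM, CM]
  k: 10
  n_repetitions: 10
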