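Per-clade fixtures: tip sets and per-species mating-system categories are
transcribed from the published per-clade descriptions; branching orders and
the *_sp_* placeholder species names are synthetic stand-ins (the full
332-taxon phylogeny is not redistributed here), constrained to be
consistent with the clade memberships and sister relationships stated in
those descriptions. Files whose topology is reconstructed rather than
copied are suffixed _synthetic.
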