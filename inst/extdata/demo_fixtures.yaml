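# Small demonstration fixture spec for `audit.R fixtures`.
seed: 42
p_registry_results: 0.2
p_text_only: 0.015
p_protocol_decoy: 0.15
p_precompletion_decoy: 0.10
p_commentary_decoy: 0.15
n_noise_citations: 25
as_of: 2016-10
sponsors:
  - name: Meridian Pharma
    class: industry
    n_trials: 40
    unreported_rate: 0.30
  - name: University Hospital
    class: other
    n_trials: 35
    unreported_rate: 0.60
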