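Package: ccloop
Title: Cortico-Cerebellar Loop Networks: Simulation, Learning and Consolidation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a leaky-rate cortical recurrent network reciprocally
    coupled to a feedforward cerebellar module (mossy fibre expansion to a
    granule layer, plastic parallel fibres). The cerebellum is trained with a
    behavioural timing-specific delta rule that makes its feedback predictive
    of future task outcomes, while cortical weights learn online with
    eligibility-trace (e-prop) gradients under configurable plasticity
    regimes. Ships generators for five synthetic tasks (line drawing,
    curl-field drawing, digit drawing, evidence accumulation, delayed
    association), cerebellar/cortical ablation schedules, context-dependent
    parallel-fibre masks for task switching, systems-consolidation rules that
    transfer cerebellar drive into recurrent cortical weights, and analysis
    tools (controllability energy, SNR decomposition, choice regression,
    selectivity and covariance-change metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    signal,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
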