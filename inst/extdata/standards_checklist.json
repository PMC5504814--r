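[
  {"feature": "Predefined treatment options", "in_system": true, "agree": true, "ipdas": true, "footnote": null},
  {"feature": "Predefined patient-important criteria", "in_system": true, "agree": true, "ipdas": true, "footnote": "a"},
  {"feature": "Expected performances for all options on all criteria", "in_system": true, "agree": false, "ipdas": true, "footnote": "b"},
  {"feature": "Patient's relative preferences for the outcomes, integrated in the mathematical calculation of expected values", "in_system": true, "agree": false, "ipdas": false, "footnote": "c"},
  {"feature": "Data collection plans", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Notifications and reminders on smartphone", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Collection of former treatment results", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Collection of current treatment results", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Collection of life events, health data and decision quality", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Measurement of treatment and monitoring fidelity", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Automatic modification of core decision components based on patient characteristics", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "The priorities of the individual patient, and relevant data from the patient, clinician and research, integrated mathematically to provide a ranking of treatments", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Direct modification of core decision components available", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Ranking of treatments based on mathematical integration includes uncertainty or quality of the evidence assessments", "in_system": true, "agree": false, "ipdas": false, "footnote": "d"},
  {"feature": "Comparison of expected performance of options", "in_system": true, "agree": false, "ipdas": true, "footnote": null},
  {"feature": "Expected performance of all options provided", "in_system": true, "agree": true, "ipdas": true, "footnote": null},
  {"feature": "Visualization of individual patient results over time", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Statistical summaries and analyzes for the individual", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Treatment strategy for the individual patient available", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Agreed, main treatments for the individual accessible", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Agreed, additional treatments for the individual accessible", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Agreed, healthy habits for the individual accessible", "in_system": true, "agree": false, "ipdas": false, "footnote": null},
  {"feature": "Support for help from collaborators integrated in system", "in_system": true, "agree": false, "ipdas": false, "footnote": null}
]
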