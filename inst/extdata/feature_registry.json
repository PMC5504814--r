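[
  {"strategy_id": 1, "strategy_label": "Find the best treatment", "feature": "Ranks all available treatments based on all available information and the patient's preferences"},
  {"strategy_id": 1, "strategy_label": "Find the best treatment", "feature": "Allows patients to see how modifying their personal preferences influence this ranking"},
  {"strategy_id": 1, "strategy_label": "Find the best treatment", "feature": "Presents head-to-head comparisons of all treatments on all included outcomes"},
  {"strategy_id": 1, "strategy_label": "Find the best treatment", "feature": "Removes treatments that are contraindicated for the specific patient automatically"},
  {"strategy_id": 1, "strategy_label": "Find the best treatment", "feature": "Removes outcomes that are irrelevant for the specific patient, automatically"},
  {"strategy_id": 1, "strategy_label": "Find the best treatment", "feature": "Integrates quantitative estimates of treatment effects from research, the patient, and the clinician"},
  {"strategy_id": 1, "strategy_label": "Find the best treatment", "feature": "Presents treatment results longitudinally together with treatment details and other relevant data"},
  {"strategy_id": 2, "strategy_label": "Find the best dosage", "feature": "Presents the effects of different dosages on subjective and objective health outcomes as graphs and statistics"},
  {"strategy_id": 2, "strategy_label": "Find the best dosage", "feature": "Presents the effects of different dosages as an integrated part of complete treatment plans"},
  {"strategy_id": 3, "strategy_label": "Increase treatment adherence", "feature": "Can remind the patient to take the treatment at all agreed times, on the smartphone"},
  {"strategy_id": 3, "strategy_label": "Increase treatment adherence", "feature": "Presents actual use over time as graphs and statistics for patients and clinicians to inspect together"},
  {"strategy_id": 3, "strategy_label": "Increase treatment adherence", "feature": "Includes snippets for day-to-day improvement of treatment, lifestyle and monitoring adherence, based on information from the last two weeks"},
  {"strategy_id": 4, "strategy_label": "Live more healthily", "feature": "Allows patients to select suggested lifestyle measures and include them in the overall treatment plan"},
  {"strategy_id": 4, "strategy_label": "Live more healthily", "feature": "Can remind the patient to follow up the lifestyle measures"},
  {"strategy_id": 4, "strategy_label": "Live more healthily", "feature": "Presents the adherence to the lifestyle measures graphically and allows inspection of their effects on subjective and objective health outcomes"},
  {"strategy_id": 4, "strategy_label": "Live more healthily", "feature": "Allows inspection of how lifestyle, defined as significant events added into the system, affects health, in graphs and from statistics"},
  {"strategy_id": 5, "strategy_label": "Get support from healthcare providers, friends and family", "feature": "Enables the patient to give healthcare providers, friends and family access to the patient's system"},
  {"strategy_id": 5, "strategy_label": "Get support from healthcare providers, friends and family", "feature": "Enables the patient to set rules regarding when others should be warned, for instance when adherence has dropped below a pre-defined level"},
  {"strategy_id": 6, "strategy_label": "Improve the decision process and decision satisfaction", "feature": "Provides information about why and how to be involved in decisions"},
  {"strategy_id": 6, "strategy_label": "Improve the decision process and decision satisfaction", "feature": "Enables patients to track the decision quality related to each specific healthcare provider on several aspects"},
  {"strategy_id": 6, "strategy_label": "Improve the decision process and decision satisfaction", "feature": "Enables patients and clinicians to make decisions based on patient-specific information integrated with information from research, condensed into graphics and statistics"}
]
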