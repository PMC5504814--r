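metric,below,severity,message
medication_adherence,90,nudge,"Medication intake was {value} over the last two weeks; a fixed daily routine (for example with breakfast) can help you stay above 90%."
medication_adherence,75,warning,"Medication intake dropped to {value} over the last two weeks; consider enabling reminders for every agreed intake time."
medication_adherence,50,urgent,"Medication intake was only {value} over the last two weeks; please review the treatment plan with your clinician."
lifestyle_adherence,90,nudge,"Lifestyle measures were followed {value} of the time over the last two weeks; scheduling them like appointments can help."
lifestyle_adherence,75,warning,"Lifestyle-measure follow-up dropped to {value} over the last two weeks; pick the one measure that matters most and protect time for it."
lifestyle_adherence,50,urgent,"Lifestyle measures were followed only {value} of the time over the last two weeks; consider simplifying the plan with your care team."
monitoring_fidelity,90,nudge,"Self-monitoring was completed {value} of scheduled days over the last two weeks; reporting at a fixed time of day can help."
monitoring_fidelity,75,warning,"Self-monitoring dropped to {value} over the last two weeks; without regular data the decision panels lose precision."
monitoring_fidelity,50,urgent,"Self-monitoring was completed on only {value} of scheduled days over the last two weeks; please restart daily reporting so results stay interpretable."
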