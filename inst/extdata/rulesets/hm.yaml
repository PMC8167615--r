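# Multimorbidity (hypertension + type 2 diabetes) merge ruleset: resolves
# redundancies and conflicts when the two single-disease plans are merged.
# Conflict rules keep the most conservative member of a conflict group.
- rule_id: HM-MERGE-EXERCISE
  disease_scope: HM
  trigger: {type: periodic, frequency_days: 30}
  condition:
    - {fact: profile.has_hm, op: "==", value: true}
  action:
    task_kind: LifestyleGuidance
    parameters:
      conflict_group: exercise
      keep: moderate_exercise
      drop: [increase_exercise]
  priority: 100

- rule_id: HM-MERGE-DIET
  disease_scope: HM
  trigger: {type: periodic, frequency_days: 30}
  condition:
    - {fact: profile.has_hm, op: "==", value: true}
  action:
    task_kind: LifestyleGuidance
    parameters:
      conflict_group: diet
      keep: balanced_diet
      drop: []
  priority: 90
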