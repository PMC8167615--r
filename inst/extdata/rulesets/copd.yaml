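# COPD care-pathway ruleset.  Stratification follows directly from the risk
# assessment (no separate classification step) and medication guidance is
# not generated by the engine for COPD.
- rule_id: COPD-RISK-01
  disease_scope: COPD
  trigger: {type: periodic, frequency_days: 90}
  condition:
    - {fact: profile.has_copd, op: "==", value: true}
  action:
    task_kind: RiskAssessment
    parameters: {disease: COPD}
  priority: 100

- rule_id: COPD-LEVEL-01
  disease_scope: COPD
  trigger: {type: periodic, frequency_days: 7}
  condition:
    - {fact: profile.has_copd, op: "==", value: true}
    - {fact: task.RiskAssessment.exists, op: "==", value: true}
  action:
    task_kind: HierarchicalManagement
    parameters: {disease: COPD, from_risk: true}
  priority: 90

- rule_id: COPD-FOLLOWUP-01
  disease_scope: COPD
  trigger: {type: periodic, frequency_days: 7}
  condition:
    - {fact: profile.has_copd, op: "==", value: true}
    - {fact: task.HierarchicalManagement.exists, op: "==", value: true}
  action:
    task_kind: RegularFollowUp
    parameters: {disease: COPD}
  priority: 80

- rule_id: COPD-WARN-01
  disease_scope: COPD
  trigger: {type: event, record_kinds: [PEF, psychological, discomfort]}
  condition:
    - {fact: warning.any_urgent, op: "==", value: true}
  action:
    task_kind: AbnormalConditionIntervention
    parameters: {disease: COPD, reason: pef_or_exacerbation}
  valid_duration_days: 3
  priority: 100

- rule_id: COPD-LIFE-01
  disease_scope: COPD
  trigger: {type: periodic, frequency_days: 30}
  condition:
    - {fact: profile.has_copd, op: "==", value: true}
  action:
    task_kind: LifestyleGuidance
    parameters:
      disease: COPD
      items: [no_smoking, regular_exercise, rehabilitation_exercise]
  priority: 60

- rule_id: COPD-EDU-01
  disease_scope: COPD
  trigger: {type: periodic, frequency_days: 30}
  condition:
    - {fact: profile.has_copd, op: "==", value: true}
  action:
    task_kind: HealthEducation
    parameters: {disease: COPD, topic: copd_basics}
  priority: 50

- rule_id: COPD-COMPL-01
  disease_scope: COPD
  trigger: {type: periodic, frequency_days: 1}
  condition:
    - {fact: profile.has_copd, op: "==", value: true}
    - {fact: compliance.low, op: "==", value: true}
  action:
    task_kind: ComplianceManagement
    parameters: {disease: COPD, action: extra_followup}
  valid_duration_days: 7
  priority: 85
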