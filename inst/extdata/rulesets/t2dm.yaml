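# Type 2 diabetes care-pathway ruleset.
- rule_id: T2DM-RISK-01
  disease_scope: T2DM
  trigger: {type: periodic, frequency_days: 180}
  condition:
    - {fact: profile.has_t2dm, op: "==", value: true}
  action:
    task_kind: RiskAssessment
    parameters: {disease: T2DM}
  priority: 100

- rule_id: T2DM-LEVEL-01
  disease_scope: T2DM
  trigger: {type: periodic, frequency_days: 7}
  condition:
    - {fact: profile.has_t2dm, op: "==", value: true}
    - {fact: task.RiskAssessment.exists, op: "==", value: true}
  action:
    task_kind: HierarchicalManagement
    parameters: {disease: T2DM}
  priority: 90

- rule_id: T2DM-FOLLOWUP-01
  disease_scope: T2DM
  trigger: {type: periodic, frequency_days: 7}
  condition:
    - {fact: profile.has_t2dm, op: "==", value: true}
    - {fact: task.HierarchicalManagement.exists, op: "==", value: true}
  action:
    task_kind: RegularFollowUp
    parameters: {disease: T2DM}
  priority: 80

- rule_id: T2DM-WARN-01
  disease_scope: T2DM
  trigger: {type: event, record_kinds: [BG]}
  condition:
    - {fact: warning.any_urgent, op: "==", value: true}
  action:
    task_kind: AbnormalConditionIntervention
    parameters: {disease: T2DM, reason: urgent_bg_or_ketone}
  valid_duration_days: 3
  priority: 100

- rule_id: T2DM-MED-01
  disease_scope: T2DM
  trigger: {type: periodic, frequency_days: 30}
  condition:
    - {fact: profile.has_t2dm, op: "==", value: true}
    - {fact: task.HierarchicalManagement.exists, op: "==", value: true}
  action:
    task_kind: MedicationGuidance
    parameters: {disease: T2DM, guidance: hypoglycemic_or_insulin_review}
  priority: 70

- rule_id: T2DM-LIFE-01
  disease_scope: T2DM
  trigger: {type: periodic, frequency_days: 30}
  condition:
    - {fact: profile.has_t2dm, op: "==", value: true}
  action:
    task_kind: LifestyleGuidance
    parameters:
      disease: T2DM
      items: [control_weight, balanced_diet, reduce_sodium,
              no_smoking_drinking, moderate_exercise, reduce_stress]
  priority: 60

- rule_id: T2DM-EDU-01
  disease_scope: T2DM
  trigger: {type: periodic, frequency_days: 30}
  condition:
    - {fact: profile.has_t2dm, op: "==", value: true}
  action:
    task_kind: HealthEducation
    parameters: {disease: T2DM, topic: diabetes_basics}
  priority: 50

- rule_id: T2DM-COMPL-01
  disease_scope: T2DM
  trigger: {type: periodic, frequency_days: 1}
  condition:
    - {fact: profile.has_t2dm, op: "==", value: true}
    - {fact: compliance.low, op: "==", value: true}
  action:
    task_kind: ComplianceManagement
    parameters: {disease: T2DM, action: extra_followup}
  valid_duration_days: 7
  priority: 85
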