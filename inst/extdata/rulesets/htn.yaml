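# Hypertension care-pathway ruleset.
# Chaining is deliberate: risk assessment enables stratification, whose
# task instance in turn enables follow-up scheduling and guidance tasks.
- rule_id: HTN-RISK-01
  disease_scope: HTN
  trigger: {type: periodic, frequency_days: 180}
  condition:
    - {fact: profile.has_htn, op: "==", value: true}
  action:
    task_kind: RiskAssessment
    parameters: {disease: HTN}
  priority: 100

- rule_id: HTN-LEVEL-01
  disease_scope: HTN
  trigger: {type: periodic, frequency_days: 7}
  condition:
    - {fact: profile.has_htn, op: "==", value: true}
    - {fact: task.RiskAssessment.exists, op: "==", value: true}
  action:
    task_kind: HierarchicalManagement
    parameters: {disease: HTN}
  priority: 90

- rule_id: HTN-FOLLOWUP-01
  disease_scope: HTN
  trigger: {type: periodic, frequency_days: 7}
  condition:
    - {fact: profile.has_htn, op: "==", value: true}
    - {fact: task.HierarchicalManagement.exists, op: "==", value: true}
  action:
    task_kind: RegularFollowUp
    parameters: {disease: HTN}
  priority: 80

- rule_id: HTN-WARN-01
  disease_scope: HTN
  trigger: {type: event, record_kinds: [BP]}
  condition:
    - {fact: warning.any_urgent, op: "==", value: true}
  action:
    task_kind: AbnormalConditionIntervention
    parameters: {disease: HTN, reason: urgent_bp}
  valid_duration_days: 3
  priority: 100

- rule_id: HTN-MED-01
  disease_scope: HTN
  trigger: {type: periodic, frequency_days: 30}
  condition:
    - {fact: profile.has_htn, op: "==", value: true}
    - {fact: task.HierarchicalManagement.exists, op: "==", value: true}
  action:
    task_kind: MedicationGuidance
    parameters: {disease: HTN, guidance: antihypertensive_review}
  priority: 70

- rule_id: HTN-LIFE-01
  disease_scope: HTN
  trigger: {type: periodic, frequency_days: 30}
  condition:
    - {fact: profile.has_htn, op: "==", value: true}
  action:
    task_kind: LifestyleGuidance
    parameters:
      disease: HTN
      items: [reduce_sodium, control_weight, no_smoking_drinking,
              increase_exercise, reduce_stress]
  priority: 60

- rule_id: HTN-EDU-01
  disease_scope: HTN
  trigger: {type: periodic, frequency_days: 30}
  condition:
    - {fact: profile.has_htn, op: "==", value: true}
  action:
    task_kind: HealthEducation
    parameters: {disease: HTN, topic: hypertension_basics}
  priority: 50

- rule_id: HTN-COMPL-01
  disease_scope: HTN
  trigger: {type: periodic, frequency_days: 1}
  condition:
    - {fact: profile.has_htn, op: "==", value: true}
    - {fact: compliance.low, op: "==", value: true}
  action:
    task_kind: ComplianceManagement
    parameters: {disease: HTN, action: extra_followup}
  valid_duration_days: 7
  priority: 85
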