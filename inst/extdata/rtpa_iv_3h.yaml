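# Built-in eligibility rule set: rt-PA intravenous thrombolysis, 3-hour window.
# Indications must all hold and no contraindication may hold for the therapy
# to be recommended. `op: flag` tests a boolean snapshot field; comparison
# rules test a numeric field against a threshold. A rule with `any_of` is
# violated/satisfied when any of its clauses holds (disjunction).
name: rtpa_iv_3h
therapy: iv_thrombolysis
time_window: 3
rules:
- id: ind-1
  kind: indication
  description: Neurological deficit attributable to ischemic stroke
  field: ischemic_deficit
  op: flag
- id: ind-2
  kind: indication
  description: Within 3 h of symptom onset (or last known well)
  field: onset_to_consult
  op: le
  threshold: 3
  units: hours
- id: ind-3
  kind: indication
  description: Age over 18 years
  field: age
  op: gt
  threshold: 18
  units: years
- id: ind-4
  kind: indication
  description: Informed consent signed by patient or family
  field: consent_signed
  op: flag
- id: contra-1
  kind: contraindication
  description: Intracranial hemorrhage
  field: intracranial_hemorrhage
  op: flag
- id: contra-2
  kind: contraindication
  description: History of intracranial hemorrhage
  field: history_ich
  op: flag
- id: contra-3
  kind: contraindication
  description: Stroke or severe head injury within 3 months
  field: stroke_or_head_injury_3mo
  op: flag
- id: contra-4
  kind: contraindication
  description: Intracranial neoplasm or giant intracranial aneurysm
  field: intracranial_neoplasm_or_aneurysm
  op: flag
- id: contra-5
  kind: contraindication
  description: Intracranial or intraspinal surgery within 3 months
  field: intracranial_spinal_surgery_3mo
  op: flag
- id: contra-6
  kind: contraindication
  description: Major surgery within 2 weeks
  field: major_surgery_2wk
  op: flag
- id: contra-7
  kind: contraindication
  description: Gastrointestinal or urinary tract bleeding within 3 weeks
  field: gi_or_urinary_bleed_3wk
  op: flag
- id: contra-8
  kind: contraindication
  description: Active visceral hemorrhage
  field: active_visceral_hemorrhage
  op: flag
- id: contra-9
  kind: contraindication
  description: Aortic arch dissection
  field: aortic_arch_dissection
  op: flag
- id: contra-10
  kind: contraindication
  description: Arterial puncture at a non-compressible site within the past week
  field: recent_difficult_arterial_puncture_1wk
  op: flag
- id: contra-11
  kind: contraindication
  description: Blood pressure above 180/100 mmHg (systolic or diastolic)
  any_of:
  - field: systolic_bp
    op: gt
    threshold: 180
    units: mmHg
  - field: diastolic_bp
    op: gt
    threshold: 100
    units: mmHg
- id: contra-12
  kind: contraindication
  description: Platelet count below 100 x 10^9/L
  field: platelet_count
  op: lt
  threshold: 100
  units: 10^9/L
- id: contra-13
  kind: contraindication
  description: Low-molecular-weight heparin within 24 h
  field: lmwh_24h
  op: flag
- id: contra-14
  kind: contraindication
  description: INR above 1.7 or prothrombin time above 15 s
  any_of:
  - field: inr
    op: gt
    threshold: 1.7
    units: ratio
  - field: pt
    op: gt
    threshold: 15
    units: seconds
- id: contra-15
  kind: contraindication
  description: Thrombin or factor Xa inhibitor within 48 h, or abnormal coagulation laboratory results
  any_of:
  - field: thrombin_or_xa_inhibitor_48h
    op: flag
  - field: abnormal_lab
    op: flag
- id: contra-16
  kind: contraindication
  description: Blood glucose below 2.8 or above 22.22 mmol/L
  any_of:
  - field: glucose
    op: lt
    threshold: 2.8
    units: mmol/L
  - field: glucose
    op: gt
    threshold: 22.22
    units: mmol/L
- id: contra-17
  kind: contraindication
  description: Large infarct area on imaging
  field: large_infarct_area
  op: flag
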