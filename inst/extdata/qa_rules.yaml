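# Question-classification rules: one per relation type. Order defines
# matching precedence (first rule with a feature-word hit wins). The
# direction says whether the entity mentioned in the question plays the
# subject or the object role of the relation; answers are its neighbors on
# the other side. Feature words are replaceable configuration; the defaults
# mix English triggers with a few Chinese ones.
- relation: DrTr
  features: [prescribed, "配合用药"]
  direction: object
  template: "Drugs prescribed as part of {entity} are {answers}."
- relation: DrAS
  features: [medication, eases, "缓解用药"]
  direction: object
  template: "Medications that ease {entity} are {answers}."
- relation: DrAD
  features: [drug, "用药"]
  direction: object
  template: "Drugs used to treat {entity} are {answers}."
- relation: TrAD
  features: [treatment, "治疗方法"]
  direction: object
  template: "Treatments for {entity} are {answers}."
- relation: TrAS
  features: [relieve, "怎么缓解"]
  direction: object
  template: "Treatments that relieve {entity} are {answers}."
- relation: TeRD
  features: [confirm, "确诊"]
  direction: object
  template: "Tests that can confirm {entity} are {answers}."
- relation: TeBD
  features: [undergo, "需要做什么检查"]
  direction: object
  template: "Tests to undergo for {entity} are {answers}."
- relation: TeRS
  features: [reveal, "查出"]
  direction: object
  template: "Tests that can reveal {entity} are {answers}."
- relation: TeAS
  features: [examination, "因症检查"]
  direction: object
  template: "Examinations taken because of {entity} are {answers}."
- relation: DIS
  features: [symptom, "症状", "临床表现"]
  direction: subject
  template: "Clinical manifestations of {entity} are {answers}."
- relation: SDD
  features: [indicate, "提示"]
  direction: subject
  template: "{entity} may indicate {answers}."
- relation: FCS
  features: [cause, "诱发"]
  direction: subject
  template: "{entity} can cause {answers}."
- relation: DM
  features: [precaution, "注意事项"]
  direction: subject
  template: "Precautions for {entity}: {answers}."
- relation: SM
  features: [advice, "建议"]
  direction: subject
  template: "Advice for {entity}: {answers}."
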