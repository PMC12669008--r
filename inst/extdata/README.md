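# Bundled reference tables

Published per-service diagnostic operating points of three commercial
mammography AI services evaluated on a large Moscow population screening
programme (663,606 examinations, 2.9% pathology prevalence; ground truth =
radiologist BI-RADS, categories 4-6 binarized to "pathology"):

- `service_metrics_youden.csv` — threshold, sensitivity, specificity and
  accuracy of each service version at its Youden-index threshold.
- `service_metrics_net_benefit.csv` — the same services at the
  NetBenefit0/NetBenefit1 intersection threshold.
- `screening_class_counts.csv` — the programme's pathology/normal class
  counts.

These are printed summary numbers, not patient-level data; the underlying
cohort is not publicly available. They serve as inputs to
`summarize_across_models()` (cross-model mean/min/max aggregates) and to the
acceptance script. Note: the AI3 rows of the two metric tables are mutually
inconsistent with any single fixed score distribution (specificity would
have to decrease as the threshold rises); they are kept exactly as
published.
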