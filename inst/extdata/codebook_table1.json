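{
  "age_group": {
    "levels": [
      {"code": "65_74", "label": "65 - 74"},
      {"code": "75_84", "label": "75 - 84"},
      {"code": "85_over", "label": "85 and over"}
    ]
  },
  "nationality": {
    "levels": [
      {"code": "japanese", "label": "Japanese"},
      {"code": "foreign", "label": "Foreign"}
    ]
  },
  "living_alone": {
    "levels": [
      {"code": "yes", "label": "Yes"},
      {"code": "no", "label": "No"}
    ]
  },
  "disability_disease": {
    "levels": [
      {"code": "physical_disability", "label": "Physical disability"},
      {"code": "mental_disability", "label": "Mental disability"},
      {"code": "intellectual_disability", "label": "Intellectual disability"},
      {"code": "psychiatric_disorder", "label": "Psychiatric disorder"},
      {"code": "other_physical_disease", "label": "Other physical diseases"},
      {"code": "alcohol_dependency", "label": "Alcoholic dependency"},
      {"code": "none", "label": "None"}
    ]
  },
  "hospitalization": {
    "levels": [
      {"code": "yes", "label": "Yes"},
      {"code": "no", "label": "No"}
    ]
  },
  "ltc_status": {
    "levels": [
      {"code": "support_need", "label": "Support need"},
      {"code": "ltc_need", "label": "Long-term care need"},
      {"code": "none", "label": "None"}
    ]
  },
  "working": {
    "levels": [
      {"code": "yes", "label": "Yes"},
      {"code": "no", "label": "No"}
    ]
  },
  "previous_pa": {
    "levels": [
      {"code": "yes", "label": "Yes"},
      {"code": "no", "label": "No"}
    ]
  },
  "reason_start": {
    "levels": [
      {"code": "decreased_income", "label": "Decreased income"},
      {"code": "disease", "label": "Disease"},
      {"code": "unemployment", "label": "Unemployment"},
      {"code": "divorce_bereavement", "label": "Divorce/bereavement"},
      {"code": "other", "label": "Other reasons"}
    ]
  },
  "facility_admission": {
    "levels": [
      {"code": "yes", "label": "Yes"},
      {"code": "no", "label": "No"}
    ]
  },
  "house_type": {
    "levels": [
      {"code": "rental", "label": "Rental house"},
      {"code": "public", "label": "Public house"},
      {"code": "own", "label": "Own house"},
      {"code": "other", "label": "Other houses"}
    ]
  },
  "income_band": {
    "levels": [
      {"code": "above_median", "label": "Above median"},
      {"code": "below_median", "label": "Below median"},
      {"code": "none", "label": "None"}
    ]
  },
  "pension_band": {
    "levels": [
      {"code": "above_median", "label": "Above median"},
      {"code": "below_median", "label": "Below median"},
      {"code": "none", "label": "None"}
    ]
  }
}
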