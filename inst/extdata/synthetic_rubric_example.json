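{
  "protocol_id": "EX-PROT-01",
  "domains": {
    "trial_design": {
      "keywords": [
        {
          "id": "parallel_group",
          "text": "two-arm parallel group",
          "weight": 3,
          "essential": true
        },
        {
          "id": "ratio_1_1",
          "text": "1:1 allocation ratio",
          "weight": 2,
          "essential": true
        },
        {
          "id": "superiority",
          "text": "superiority trial",
          "weight": 2,
          "essential": false
        },
        {
          "id": "protocol_changes",
          "text": "no important changes after commencement",
          "weight": 1,
          "essential": false
        }
      ]
    },
    "randomization": {
      "keywords": [
        {
          "id": "computer_generated",
          "text": "Computer generated",
          "weight": 3,
          "essential": true
        },
        {
          "id": "blocks_of_4",
          "text": "blocks of 4",
          "weight": 2,
          "essential": false
        },
        {
          "id": "ratio_1_1",
          "text": "1:1",
          "weight": 1,
          "essential": false
        },
        {
          "id": "strat_site",
          "text": "stratification on site",
          "weight": 2,
          "essential": true
        }
      ]
    },
    "blinding": {
      "keywords": [
        {
          "id": "double_blind",
          "text": "double blind",
          "weight": 3,
          "essential": true
        },
        {
          "id": "placebo_matched",
          "text": "matching placebo",
          "weight": 2,
          "essential": false
        },
        {
          "id": "who_blinded",
          "text": "participants carers and assessors blinded",
          "weight": 2,
          "essential": true
        }
      ]
    },
    "participants": {
      "keywords": [
        {
          "id": "adults_18",
          "text": "adults aged 18 years or older",
          "weight": 2,
          "essential": true
        },
        {
          "id": "diagnosis_confirmed",
          "text": "diagnosis confirmed by imaging",
          "weight": 3,
          "essential": true
        },
        {
          "id": "exclusion_pregnancy",
          "text": "pregnant women excluded",
          "weight": 1,
          "essential": false
        },
        {
          "id": "recruitment_centres",
          "text": "recruited in 12 centres",
          "weight": 1,
          "essential": false
        }
      ]
    },
    "interventions": {
      "keywords": [
        {
          "id": "dose_10mg",
          "text": "10 mg orally",
          "weight": 3,
          "essential": true
        },
        {
          "id": "once_daily",
          "text": "once daily",
          "weight": 2,
          "essential": true
        },
        {
          "id": "duration_12w",
          "text": "for 12 weeks",
          "weight": 2,
          "essential": false
        },
        {
          "id": "comparator_placebo",
          "text": "identical placebo",
          "weight": 2,
          "essential": true
        }
      ]
    },
    "outcomes": {
      "keywords": [
        {
          "id": "primary_6m",
          "text": "primary outcome at 6 months",
          "weight": 3,
          "essential": true
        },
        {
          "id": "scale_0_100",
          "text": "0 to 100 scale",
          "weight": 2,
          "essential": true
        },
        {
          "id": "assessor_central",
          "text": "centrally assessed",
          "weight": 1,
          "essential": false
        },
        {
          "id": "secondary_listed",
          "text": "secondary outcomes",
          "weight": 1,
          "essential": false
        }
      ]
    }
  }
}
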