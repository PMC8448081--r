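{
  "instruments": {
    "mhcsf": {
      "name": "mhcsf",
      "item_count": 14,
      "item_min": 0,
      "item_max": 5,
      "scoring_rule": "sum",
      "direction": "higher_is_better",
      "reverse_items": [],
      "subscales": {
        "emotional": [1, 2, 3],
        "social": [4, 5, 6, 7, 8],
        "psychological": [9, 10, 11, 12, 13, 14]
      }
    },
    "swls": {
      "name": "swls",
      "item_count": 5,
      "item_min": 1,
      "item_max": 7,
      "scoring_rule": "sum",
      "direction": "higher_is_better",
      "reverse_items": [],
      "subscales": {}
    },
    "dass21": {
      "name": "dass21",
      "item_count": 21,
      "item_min": 0,
      "item_max": 3,
      "scoring_rule": "sum_times_two",
      "direction": "lower_is_better",
      "reverse_items": [],
      "subscales": {
        "depression": [3, 5, 10, 13, 16, 17, 21],
        "anxiety": [2, 4, 7, 9, 15, 19, 20],
        "stress": [1, 6, 8, 11, 12, 14, 18]
      }
    },
    "brs": {
      "name": "brs",
      "item_count": 6,
      "item_min": 1,
      "item_max": 5,
      "scoring_rule": "mean",
      "direction": "higher_is_better",
      "reverse_items": [2, 4, 6],
      "subscales": {}
    }
  },
  "outcomes": {
    "overall_wellbeing": {
      "instrument": "mhcsf",
      "subscale": null,
      "direction": "higher_is_better",
      "score_min": 0,
      "score_max": 70,
      "cutoffs": [
        {"label": "low", "lower": 0},
        {"label": "high", "lower": 48}
      ],
      "problematic_labels": ["low"]
    },
    "life_satisfaction": {
      "instrument": "swls",
      "subscale": null,
      "direction": "higher_is_better",
      "score_min": 5,
      "score_max": 35,
      "cutoffs": [
        {"label": "low", "lower": 5},
        {"label": "high", "lower": 20}
      ],
      "problematic_labels": ["low"]
    },
    "dass_depression": {
      "instrument": "dass21",
      "subscale": "depression",
      "direction": "lower_is_better",
      "score_min": 0,
      "score_max": 42,
      "cutoffs": [
        {"label": "normal", "lower": 0},
        {"label": "mild", "lower": 10},
        {"label": "moderate", "lower": 14},
        {"label": "severe", "lower": 21},
        {"label": "extremely_severe", "lower": 28}
      ],
      "problematic_labels": ["mild", "moderate", "severe", "extremely_severe"]
    },
    "dass_anxiety": {
      "instrument": "dass21",
      "subscale": "anxiety",
      "direction": "lower_is_better",
      "score_min": 0,
      "score_max": 42,
      "cutoffs": [
        {"label": "normal", "lower": 0},
        {"label": "mild", "lower": 8},
        {"label": "moderate", "lower": 10},
        {"label": "severe", "lower": 15},
        {"label": "extremely_severe", "lower": 20}
      ],
      "problematic_labels": ["mild", "moderate", "severe", "extremely_severe"]
    },
    "dass_stress": {
      "instrument": "dass21",
      "subscale": "stress",
      "direction": "lower_is_better",
      "score_min": 0,
      "score_max": 42,
      "cutoffs": [
        {"label": "normal", "lower": 0},
        {"label": "mild", "lower": 15},
        {"label": "moderate", "lower": 19},
        {"label": "severe", "lower": 26},
        {"label": "extremely_severe", "lower": 34}
      ],
      "problematic_labels": ["mild", "moderate", "severe", "extremely_severe"]
    },
    "resilience": {
      "instrument": "brs",
      "subscale": null,
      "direction": "higher_is_better",
      "score_min": 1,
      "score_max": 5,
      "cutoffs": [
        {"label": "low", "lower": 1},
        {"label": "normal", "lower": 3},
        {"label": "high", "lower": 4.31}
      ],
      "problematic_labels": ["low"]
    }
  }
}
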