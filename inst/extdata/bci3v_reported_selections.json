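{
  "_comment": "Published per-user feature subsets selected on BCI Competition III Data Set V by each criterion+wrapper combination; used as inputs for the unified-model construction and subset-size summaries.",
  "n_features": 96,
  "users": {
    "user1": {
      "statistic+order": [38, 2],
      "statistic+gmdh": [38, 2, 31],
      "fuzzy+order": [26, 27, 25, 38, 2, 3, 61, 39, 62],
      "fuzzy+gmdh": [38, 2, 27, 62]
    },
    "user2": {
      "statistic+order": [26, 2, 1],
      "statistic+gmdh": [2, 26, 5],
      "fuzzy+order": [26, 2, 1],
      "fuzzy+gmdh": [2, 26, 27, 61]
    },
    "user3": {
      "statistic+order": [39, 3, 1, 2, 4, 31],
      "statistic+gmdh": [4, 3, 30],
      "fuzzy+order": [3, 74, 39, 4, 73],
      "fuzzy+gmdh": [4, 3, 49]
    }
  }
}
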