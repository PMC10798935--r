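{
  "sex": "female",
  "age": 29,
  "height": 167,
  "weight": 61,
  "activity_level": "light",
  "dietary_categories": "vegetarian",
  "allergies": [],
  "dislikes": "zucchini",
  "likes": ["rice", "pasta", "cherry_tomato", "lentils"]
}
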