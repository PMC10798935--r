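subject: This recipe
templates:
  item_user: '{subject} {clauses}.'
  contrastive: '{subject} is suggested instead of {counter} that {neg_clauses}; this
    recipe {pos_clauses}.'
phrases:
  protein:
    sufficient: provides sufficient protein
    low: is light on protein
    high: is rather high in protein
    worse: provides a poorer protein balance
    better: keeps protein at a healthy level
  lipids:
    sufficient: has a balanced amount of fats
    low: is low in fat
    high: is high in fat
    worse: contains a substantially higher amount of fats
    better: keeps fats in a healthy range
  carbohydrates:
    sufficient: provides a balanced amount of carbohydrates
    low: is low in carbohydrates
    high: is high in carbohydrates
    worse: carries a less healthy amount of carbohydrates
    better: keeps carbohydrates in a healthy range
  cholesterol:
    sufficient: keeps cholesterol within a healthy range
    low: is very low in cholesterol
    high: is high in cholesterol
    worse: contains a substantially higher amount of cholesterol
    better: keeps cholesterol in check
  sodium:
    sufficient: has a reasonable amount of salt
    low: is low in salt
    high: is high in salt
    worse: contains a substantially higher amount of salt
    better: keeps salt at a healthy level
  saturated_fat:
    sufficient: keeps saturated fats within a healthy range
    low: is low in saturated fats
    high: is high in saturated fats
    worse: contains a substantially higher amount of saturated fats
    better: keeps saturated fats low
  calories:
    appropriate: matches your calorie needs for this meal
    low: is a little light on calories for you
    high: exceeds your calorie needs for this meal
    worse: fits your calorie needs less well
    better: fits your calorie needs better
  rating:
    high: is highly rated by other users
    moderate: is decently rated by other users
    low: has modest ratings from other users
    worse: is rated lower by other users
    better: is better appreciated by other users
  taste:
    worse: matches your ingredient preferences less
    better: matches your ingredient preferences better
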