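classes:
- id: almonds
  name: Almonds
  parent: nuts_seeds
- id: animal_products
  name: Animal products
  parent: food
- id: apples
  name: Apples
  parent: fruits
- id: bananas
  name: Bananas
  parent: fruits
- id: basil
  name: Basil
  parent: herbs_spices
- id: beans
  name: Beans
  parent: legumes
- id: beef
  name: Beef
  parent: meat
- id: berries
  name: Berries
  parent: fruits
- id: blueberry
  name: Blueberry
  parent: berries
- id: bread
  name: Bread
  parent: wheat
- id: butter
  name: Butter
  parent: dairy
- id: carrots
  name: Carrots
  parent: vegetables
- id: cheddar
  name: Cheddar
  parent: cheese
- id: cheese
  name: Cheese
  parent: dairy
- id: cherry_tomato
  name: Cherry tomato
  parent: tomatoes
- id: chicken
  name: Chicken
  parent: poultry
- id: chickpeas
  name: Chickpeas
  parent: legumes
- id: chili
  name: Chili
  parent: herbs_spices
- id: citrus
  name: Citrus
  parent: fruits
- id: corn
  name: Corn
  parent: grains
- id: dairy
  name: Dairy
  parent: animal_products
- id: eggs
  name: Eggs
  parent: animal_products
- id: fish
  name: Fish
  parent: seafood
- id: food
  name: Food
- id: fruits
  name: Fruits
  parent: plant_products
- id: garlic
  name: Garlic
  parent: herbs_spices
- id: grains
  name: Grains
  parent: plant_products
- id: herbs_spices
  name: Herbs and spices
  parent: plant_products
- id: honey
  name: Honey
  parent: animal_products
- id: kale
  name: Kale
  parent: leafy_greens
- id: lamb
  name: Lamb
  parent: meat
- id: leafy_greens
  name: Leafy greens
  parent: vegetables
- id: legumes
  name: Legumes
  parent: plant_products
- id: lemon
  name: Lemon
  parent: citrus
- id: lentils
  name: Lentils
  parent: legumes
- id: meat
  name: Meat
  parent: animal_products
- id: milk
  name: Milk
  parent: dairy
- id: mozzarella
  name: Mozzarella
  parent: cheese
- id: mushrooms
  name: Mushrooms
  parent: vegetables
- id: nuts_seeds
  name: Nuts and seeds
  parent: plant_products
- id: oats
  name: Oats
  parent: grains
- id: oils
  name: Oils
  parent: plant_products
- id: olive_oil
  name: Olive oil
  parent: oils
- id: onions
  name: Onions
  parent: vegetables
- id: orange
  name: Orange
  parent: citrus
- id: pasta
  name: Pasta
  parent: wheat
- id: peanuts
  name: Peanuts
  parent: nuts_seeds
- id: peppers
  name: Peppers
  parent: vegetables
- id: plant_products
  name: Plant products
  parent: food
- id: plum_tomato
  name: Plum tomato
  parent: tomatoes
- id: pork
  name: Pork
  parent: meat
- id: poultry
  name: Poultry
  parent: meat
- id: rice
  name: Rice
  parent: grains
- id: salmon
  name: Salmon
  parent: fish
- id: seafood
  name: Seafood
  parent: animal_products
- id: sesame
  name: Sesame
  parent: nuts_seeds
- id: shellfish
  name: Shellfish
  parent: seafood
- id: shrimp
  name: Shrimp
  parent: shellfish
- id: soy
  name: Soy
  parent: legumes
- id: spinach
  name: Spinach
  parent: leafy_greens
- id: strawberry
  name: Strawberry
  parent: berries
- id: tofu
  name: Tofu
  parent: soy
- id: tomatoes
  name: Tomatoes
  parent: vegetables
- id: tuna
  name: Tuna
  parent: fish
- id: turkey
  name: Turkey
  parent: poultry
- id: vegetables
  name: Vegetables
  parent: plant_products
- id: walnuts
  name: Walnuts
  parent: nuts_seeds
- id: wheat
  name: Wheat
  parent: grains
- id: yogurt
  name: Yogurt
  parent: dairy
- id: zucchini
  name: Zucchini
  parent: vegetables
does_not_eat:
  halal:
  - pork
  kosher:
  - pork
  - shellfish
  lactose_intolerant:
  - dairy
  pescatarian:
  - meat
  vegan:
  - animal_products
  vegetarian:
  - meat
  - seafood
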