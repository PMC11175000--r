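{
  "comment": "Synthetic respondent archetypes. Item means are weekly frequencies; the md archetype sits in every favourable branch of the scoring matrix (mid-interval where the branch is an interval), the wd archetype in unfavourable representative values. Dispersion d gives item variance mu/2 + d*mu^2 under the half-serving negative-binomial model.",
  "dispersion": 0.5,
  "female_prob": 0.7,
  "age": {
    "young": {"mean": 22.91, "sd": 2.25, "min": 18, "max": 30},
    "old": {"mean": 56.33, "sd": 17.43, "min": 31, "max": 95},
    "weights": [145, 68]
  },
  "archetypes": {
    "md": {
      "item_means": {
        "fruit_medium_large": 10, "fruit_small": 9, "dried_fruit": 2,
        "cooked_vegetables": 10, "raw_vegetables": 8, "salad": 8,
        "potatoes": 2, "french_fries": 0.5,
        "breakfast_cereals": 4, "loaf_bread": 1, "fresh_bread": 10,
        "bread_substitutes": 0.5, "focaccia_bread": 0.5, "pizza": 1,
        "rice_other_cereals": 7, "pasta": 10, "cookies": 1,
        "sweets_cakes_pastries": 1,
        "cow_milk": 5, "milk_products": 4, "fresh_cheese": 3,
        "seasoned_cheese": 2,
        "white_meat": 2, "red_meat": 1, "ultra_processed_food": 0.5,
        "fresh_fish": 1.5, "tinned_fish": 1, "eggs": 3, "legumes": 3,
        "soda": 0, "wine": 3, "beer": 0.5, "cocktail": 0, "spirits": 0,
        "fast_food": 0, "salted_snack": 0, "frozen_foods": 0.5,
        "ready_to_eat_meals": 0.5, "breakfast_croissant_cappuccino": 0.5
      },
      "behavior_favorable_prob": 0.9,
      "meal_time": {"mean": 40, "sd": 10},
      "dining_out_mean": 1.0,
      "portion_probs": {"small": 0.25, "standard": 0.55, "large": 0.2}
    },
    "wd": {
      "item_means": {
        "fruit_medium_large": 3, "fruit_small": 1, "dried_fruit": 0.5,
        "cooked_vegetables": 3, "raw_vegetables": 1.5, "salad": 1.5,
        "potatoes": 1, "french_fries": 2,
        "breakfast_cereals": 1, "loaf_bread": 5, "fresh_bread": 2,
        "bread_substitutes": 3, "focaccia_bread": 2, "pizza": 2,
        "rice_other_cereals": 2, "pasta": 5, "cookies": 3,
        "sweets_cakes_pastries": 3,
        "cow_milk": 2, "milk_products": 1, "fresh_cheese": 2,
        "seasoned_cheese": 2,
        "white_meat": 4, "red_meat": 4, "ultra_processed_food": 3,
        "fresh_fish": 0.5, "tinned_fish": 0.5, "eggs": 5.5, "legumes": 1,
        "soda": 5, "wine": 0.5, "beer": 2, "cocktail": 1.5, "spirits": 1,
        "fast_food": 2, "salted_snack": 3, "frozen_foods": 2,
        "ready_to_eat_meals": 2, "breakfast_croissant_cappuccino": 4
      },
      "behavior_favorable_prob": 0.1,
      "meal_time": {"mean": 20, "sd": 8},
      "dining_out_mean": 5.0,
      "portion_probs": {"small": 0.15, "standard": 0.45, "large": 0.4}
    }
  }
}
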