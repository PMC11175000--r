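{
  "comment": "MEDILITE group rules: class md_typical / non_md / alcohol, the MEDOC items (or behaviour) feeding each group, and the two cut points (servings/week; glasses/day for alcohol) separating lowest / middle / highest consumption.",
  "groups": [
    {"group_id": "fruit", "group_class": "md_typical",
     "items": ["fruit_medium_large", "fruit_small", "dried_fruit"],
     "cuts": [10.5, 17.5]},
    {"group_id": "vegetables", "group_class": "md_typical",
     "items": ["cooked_vegetables", "raw_vegetables", "salad"],
     "cuts": [14, 17.5]},
    {"group_id": "legumes", "group_class": "md_typical",
     "items": ["legumes"], "cuts": [1, 2]},
    {"group_id": "cereals", "group_class": "md_typical",
     "items": ["breakfast_cereals", "fresh_bread", "rice_other_cereals", "pasta"],
     "cuts": [14, 21]},
    {"group_id": "fish", "group_class": "md_typical",
     "items": ["fresh_fish", "tinned_fish"], "cuts": [1.5, 2.5]},
    {"group_id": "meat", "group_class": "non_md",
     "items": ["red_meat", "white_meat", "ultra_processed_food"],
     "cuts": [7, 10.5]},
    {"group_id": "dairy", "group_class": "non_md",
     "items": ["cow_milk", "milk_products", "fresh_cheese", "seasoned_cheese"],
     "cuts": [7, 10.5]},
    {"group_id": "olive_oil", "group_class": "md_typical",
     "behavior": "olive_oil"},
    {"group_id": "alcohol", "group_class": "alcohol",
     "items": ["wine", "beer", "cocktail", "spirits"],
     "cuts": [1, 2], "unit": "glasses_per_day"}
  ]
}
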