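# Stoplight tier thresholds, per serving: saturated fat (g), sodium (mg),
# added sugar (g). green_max / yellow_max cutoffs; a value above yellow_max is
# red. A missing nutrient block means "no threshold" for that category.
#
# SYNTHETIC STAND-IN. These cutoffs are built from FDA low/moderate
# nutrient-content claim levels so that the shipped pipeline is runnable; they
# are NOT a transcription of the published HER Guidelines tables. Transcribe
# the official per-category values over this file before ranking real
# inventory. Condiments/cooking staples and miscellaneous foods are never
# ranked, matching the guidelines.
fruits_vegetables:
  ranked: true
  sat_fat:     {green_max: 1, yellow_max: 3}
  sodium:      {green_max: 140, yellow_max: 480}
  added_sugar: {green_max: 0, yellow_max: 6}
grains:
  ranked: true
  sat_fat:     {green_max: 1, yellow_max: 3}
  sodium:      {green_max: 230, yellow_max: 480}
  added_sugar: {green_max: 6, yellow_max: 12}
protein:
  ranked: true
  sat_fat:     {green_max: 2, yellow_max: 5}
  sodium:      {green_max: 230, yellow_max: 480}
  added_sugar: {green_max: 0, yellow_max: 6}
dairy:
  ranked: true
  sat_fat:     {green_max: 3, yellow_max: 6}
  sodium:      {green_max: 230, yellow_max: 480}
  added_sugar: {green_max: 6, yellow_max: 12}
non_dairy_alternatives:
  ranked: true
  sat_fat:     {green_max: 3, yellow_max: 6}
  sodium:      {green_max: 230, yellow_max: 480}
  added_sugar: {green_max: 6, yellow_max: 12}
beverages:
  ranked: true
  sat_fat:     {green_max: 1, yellow_max: 3}
  sodium:      {green_max: 140, yellow_max: 480}
  added_sugar: {green_max: 0, yellow_max: 12}
mixed_dishes:
  ranked: true
  sat_fat:     {green_max: 3, yellow_max: 6}
  sodium:      {green_max: 480, yellow_max: 600}
  added_sugar: {green_max: 6, yellow_max: 12}
snacks:
  ranked: true
  sat_fat:     {green_max: 2, yellow_max: 5}
  sodium:      {green_max: 140, yellow_max: 230}
  added_sugar: {green_max: 6, yellow_max: 12}
desserts:
  ranked: true
  sat_fat:     {green_max: 2, yellow_max: 5}
  sodium:      {green_max: 230, yellow_max: 480}
  added_sugar: {green_max: 6, yellow_max: 12}
condiments_cooking_staples:
  ranked: false
miscellaneous:
  ranked: false
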