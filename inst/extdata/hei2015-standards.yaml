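# HEI-2015 component scoring standards.
# kind: adequacy (more density -> more points) or moderation (less -> more).
# basis: per_1000_kcal (constituent amount x 1000 / energy),
#        percent_of_energy (constituent grams x kcal_per_gram x 100 / energy),
#        fatty_acid_ratio ((mufa + pufa) / sfa).
# standard_for_max: density at/beyond which full points are awarded
#                   (at/below, for moderation components).
# standard_for_min: density at/below (adequacy) or at/beyond (moderation)
#                   which zero points are awarded.
# Units follow the constituent fields: cup-eq or oz-eq per 1000 kcal, mg per
# 1000 kcal for sodium, percent of energy for added sugar / saturated fat.
components:
  - name: total_fruits
    max_points: 5
    kind: adequacy
    basis: per_1000_kcal
    constituent: total_fruit
    standard_for_max: 0.8
    standard_for_min: 0
  - name: whole_fruits
    max_points: 5
    kind: adequacy
    basis: per_1000_kcal
    constituent: whole_fruit
    standard_for_max: 0.4
    standard_for_min: 0
  - name: total_vegetables
    max_points: 5
    kind: adequacy
    basis: per_1000_kcal
    constituent: total_veg
    standard_for_max: 1.1
    standard_for_min: 0
  - name: greens_and_beans
    max_points: 5
    kind: adequacy
    basis: per_1000_kcal
    constituent: greens_beans
    standard_for_max: 0.2
    standard_for_min: 0
  - name: whole_grains
    max_points: 10
    kind: adequacy
    basis: per_1000_kcal
    constituent: whole_grain
    standard_for_max: 1.5
    standard_for_min: 0
  - name: dairy
    max_points: 10
    kind: adequacy
    basis: per_1000_kcal
    constituent: dairy
    standard_for_max: 1.3
    standard_for_min: 0
  - name: total_protein_foods
    max_points: 5
    kind: adequacy
    basis: per_1000_kcal
    constituent: total_protein
    standard_for_max: 2.5
    standard_for_min: 0
  - name: seafood_and_plant_proteins
    max_points: 5
    kind: adequacy
    basis: per_1000_kcal
    constituent: seafood_plant_protein
    standard_for_max: 0.8
    standard_for_min: 0
  - name: fatty_acids
    max_points: 10
    kind: adequacy
    basis: fatty_acid_ratio
    standard_for_max: 2.5
    standard_for_min: 1.2
  - name: refined_grains
    max_points: 10
    kind: moderation
    basis: per_1000_kcal
    constituent: refined_grain
    standard_for_max: 1.8
    standard_for_min: 4.3
  - name: sodium
    max_points: 10
    kind: moderation
    basis: per_1000_kcal
    constituent: sodium
    standard_for_max: 1100
    standard_for_min: 2000
  - name: added_sugars
    max_points: 10
    kind: moderation
    basis: percent_of_energy
    constituent: added_sugar
    kcal_per_gram: 4
    standard_for_max: 6.5
    standard_for_min: 26
  - name: saturated_fats
    max_points: 10
    kind: moderation
    basis: percent_of_energy
    constituent: sfa
    kcal_per_gram: 9
    standard_for_max: 8
    standard_for_min: 16
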