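# Default species-level ecosystem service contribution matrix for crop
# pollination. Importance reflects how much the species matters for crop
# pollination (driven by the dependence of the crops it pollinates on
# animal-mediated pollination); certainty reflects the strength and
# taxonomic resolution of the evidence. Each (importance, certainty) cell
# maps to a low/medium/high contribution group. The grid is editable:
# any matrix with ordered axes and a complete, importance-monotone cell
# map is accepted by load_matrix().
importance_levels: [negligible, low, medium, high, very_high]
certainty_levels: [low, medium, high]
groups: [low, medium, high]
cells:
  - {importance: negligible, certainty: low,    group: low,
     rule: "No pollination evidence; evidence base weakest."}
  - {importance: negligible, certainty: medium, group: low,
     rule: "No pollination evidence at moderate evidence strength."}
  - {importance: negligible, certainty: high,   group: low,
     rule: "Strong evidence the taxon does not pollinate (e.g. non-flower-visiting)."}
  - {importance: low,        certainty: low,    group: low,
     rule: "Flower visitation only, or possible (visitor-only) genus-level crop records for crops with little dependence on animal pollination."}
  - {importance: low,        certainty: medium, group: low,
     rule: "Pollen transport evidence, or possible species-level crop records, for low-dependence crops."}
  - {importance: low,        certainty: high,   group: low,
     rule: "Confirmed species-level pollinator of crops with little dependence on animal pollination."}
  - {importance: medium,     certainty: low,    group: low,
     rule: "Weak (visitation-only or low-confidence genus) evidence of pollination of moderately dependent crops or flowers generally."}
  - {importance: medium,     certainty: medium, group: medium,
     rule: "Genus-level confirmed pollination, or species-level possible pollination, of moderately dependent crops or flowers generally."}
  - {importance: medium,     certainty: high,   group: medium,
     rule: "Experimentally confirmed pollination (flowers generally) or species-level true pollinator of moderately dependent crops."}
  - {importance: high,       certainty: low,    group: medium,
     rule: "Possible genus-level pollinator of crops with great dependence on animal pollination."}
  - {importance: high,       certainty: medium, group: medium,
     rule: "Genus-level true pollinator, or species-level possible pollinator, of greatly dependent crops."}
  - {importance: high,       certainty: high,   group: high,
     rule: "Species-level true pollinator with animal pollination of great impact for over half of its crops."}
  - {importance: very_high,  certainty: low,    group: medium,
     rule: "Possible genus-level pollinator of crops for which animal pollination is essential."}
  - {importance: very_high,  certainty: medium, group: high,
     rule: "Genus-level true pollinator, or species-level possible pollinator, of essentially dependent crops."}
  - {importance: very_high,  certainty: high,   group: high,
     rule: "Species-level true pollinator with animal pollination essential for over half of its crops."}
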