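# Metabolizable-energy conversion parameters per feed resource.
# proper_use: maximum fraction of the resource usable without degrading the
#   resource base (for browse it is the take-70%-leave-30% rule times the 55%
#   availability factor, 0.70 * 0.55 rounded to 0.38).
# me_min/me_max/me_avg: MJ ME per kg dry matter; the central pipeline uses
#   me_avg, min/max feed the optional uncertainty band.
decay_per_month: 0.08        # post-harvest nutritive decay, residues only
grazing_uplift: 0.076        # productivity gain of managed grazing, forage only
wet_season_forage_share: 0.80
feeds:
  - {feed_class: forage,            part: whole, zone: sahelian, proper_use: 0.55, me_min: 5.8, me_max: 6.4, me_avg: 6.1}
  - {feed_class: forage,            part: whole, zone: sudanian, proper_use: 0.55, me_min: 6.2, me_max: 6.8, me_avg: 6.5}
  - {feed_class: browse,            part: whole, zone: sahelian, proper_use: 0.38, me_min: 5.8, me_max: 6.2, me_avg: 6.0}
  - {feed_class: browse,            part: whole, zone: sudanian, proper_use: 0.38, me_min: 8.0, me_max: 8.2, me_avg: 8.1}
  - {feed_class: residue_groundnut, part: whole, zone: both,     proper_use: 1.00, me_min: 7.2, me_max: 9.3, me_avg: 8.5}
  - {feed_class: residue_maize,     part: stem,  zone: both,     proper_use: 0.10, me_min: 5.7, me_max: 6.3, me_avg: 6.0}
  - {feed_class: residue_maize,     part: leaf,  zone: both,     proper_use: 0.76, me_min: 5.9, me_max: 8.3, me_avg: 7.1}
  - {feed_class: residue_millet,    part: stem,  zone: both,     proper_use: 0.10, me_min: 5.2, me_max: 6.0, me_avg: 5.6}
  - {feed_class: residue_millet,    part: leaf,  zone: both,     proper_use: 0.76, me_min: 6.8, me_max: 9.4, me_avg: 8.1}
  - {feed_class: residue_sorghum,   part: stem,  zone: both,     proper_use: 0.10, me_min: 5.9, me_max: 6.5, me_avg: 6.2}
  - {feed_class: residue_sorghum,   part: leaf,  zone: both,     proper_use: 0.76, me_min: 5.9, me_max: 6.9, me_avg: 6.4}
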