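{
  "schema": "forestcl tree record v1",
  "columns": [
    {"name": "tree_id", "type": "string", "unit": null,
     "description": "unique tree identifier"},
    {"name": "species", "type": "string", "unit": null,
     "description": "species code"},
    {"name": "division", "type": "string", "unit": null,
     "description": "ecoregion Division code (e.g. 21..41)"},
    {"name": "plot_id", "type": "string", "unit": null,
     "description": "plot identifier"},
    {"name": "size_kgC", "type": "number", "unit": "kg C",
     "description": "aboveground carbon of the tree; > 0"},
    {"name": "growth_kgC_yr", "type": "number", "unit": "kg C tree-1 yr-1",
     "description": "growth rate between censuses; may be negative; empty for survival-only records"},
    {"name": "survived", "type": "integer", "unit": null,
     "description": "1 if alive at the second census, 0 if dead; empty for growth-only records"},
    {"name": "dt_yr", "type": "number", "unit": "yr",
     "description": "census interval; > 0"},
    {"name": "ba_m2ha", "type": "number", "unit": "m2 ha-1",
     "description": "plot basal area; > 0"},
    {"name": "bal_m2ha", "type": "number", "unit": "m2 ha-1",
     "description": "basal area of trees larger than this tree; 0 <= BAL <= BA"},
    {"name": "temp_K", "type": "number", "unit": "K",
     "description": "mean annual temperature over the census interval"},
    {"name": "precip_dm", "type": "number", "unit": "dm",
     "description": "total annual precipitation over the census interval"},
    {"name": "ndep_kgN_ha_yr", "type": "number", "unit": "kg N ha-1 yr-1",
     "description": "mean total N deposition over the census interval"},
    {"name": "sdep_kgS_ha_yr", "type": "number", "unit": "kg S ha-1 yr-1",
     "description": "mean total S deposition over the census interval"},
    {"name": "status", "type": "string", "unit": null,
     "description": "optional: 'measured', 'harvested', or 'dead_both'; harvested and dead-at-both-censuses records are excluded from the survival analysis"}
  ]
}
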