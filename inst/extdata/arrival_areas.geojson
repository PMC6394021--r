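{
  "type": "FeatureCollection",
  "note": "Observation regions for first-arrival diagnostics along the eastern Atlantic and western Mediterranean. The Mauritania box is the published bycatch-report zone; all other polygons are documented approximations extending roughly 150 km off the coastal stretches where strandings are reported.",
  "features": [
    {
      "type": "Feature",
      "properties": { "name": "mauritania", "provenance": "published box [20-30W; 11-22N]" },
      "geometry": { "type": "Polygon", "coordinates": [[
        [-30.0, 11.0], [-20.0, 11.0], [-20.0, 22.0], [-30.0, 22.0], [-30.0, 11.0]
      ]] }
    },
    {
      "type": "Feature",
      "properties": { "name": "portugal", "provenance": "approximate, ~150 km off the Portuguese coast" },
      "geometry": { "type": "Polygon", "coordinates": [[
        [-11.0, 36.8], [-8.6, 36.8], [-8.6, 42.0], [-11.0, 42.0], [-11.0, 36.8]
      ]] }
    },
    {
      "type": "Feature",
      "properties": { "name": "gulf_of_cadiz", "provenance": "approximate, Gulf of Cadiz" },
      "geometry": { "type": "Polygon", "coordinates": [[
        [-9.0, 35.5], [-5.6, 35.5], [-5.6, 37.3], [-9.0, 37.3], [-9.0, 35.5]
      ]] }
    },
    {
      "type": "Feature",
      "properties": { "name": "tunisia", "provenance": "approximate, ~150 km off the eastern Tunisian coast" },
      "geometry": { "type": "Polygon", "coordinates": [[
        [9.8, 33.0], [12.5, 33.0], [12.5, 37.5], [9.8, 37.5], [9.8, 33.0]
      ]] }
    },
    {
      "type": "Feature",
      "properties": { "name": "bay_of_biscay", "provenance": "approximate, ~150 km off the Biscay coast" },
      "geometry": { "type": "Polygon", "coordinates": [[
        [-5.2, 43.2], [-0.8, 43.2], [-0.8, 47.0], [-5.2, 47.0], [-5.2, 43.2]
      ]] }
    },
    {
      "type": "Feature",
      "properties": { "name": "galicia", "provenance": "approximate, ~150 km off the Galician coast" },
      "geometry": { "type": "Polygon", "coordinates": [[
        [-10.8, 42.0], [-7.8, 42.0], [-7.8, 44.2], [-10.8, 44.2], [-10.8, 42.0]
      ]] }
    }
  ]
}
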