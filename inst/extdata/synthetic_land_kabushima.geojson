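{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": {"name": "synthetic mainland west of the gull colony"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [140.60, 40.05],
            [141.52, 40.05],
            [141.52, 41.05],
            [140.60, 41.05],
            [140.60, 40.05]
          ]
        ]
      }
    },
    {
      "type": "Feature",
      "properties": {"name": "synthetic offshore islet"},
      "geometry": {
        "type": "Polygon",
        "coordinates": [
          [
            [141.70, 40.60],
            [141.76, 40.60],
            [141.76, 40.65],
            [141.70, 40.65],
            [141.70, 40.60]
          ]
        ]
      }
    }
  ]
}
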