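{
  "comment": "Published sample rim descriptor lists, one per rim class, recorded verbatim as (re, im) pairs in their printed order. The source does not name the frequency index of each pair; the 'indices' field is this package's documented assumption (ascending |k| starting at 2, with the dominant k = 1, -1, 0 terms printed last, consistent with the large trailing magnitudes). These fixtures serve serialization round-trip and descriptor-space flip tests only; they are not part of the morphable shape database.",
  "entries": [
    {
      "id": "sample_rectangular",
      "class": "rectangular_symmetric",
      "n_points": 64,
      "indices": [2, -2, 3, -3, 4, -4, 5, -5, 6, -6, 7, 1, -1, 0],
      "re": [4430, -57.3, 1110, -151, 37.1, -88.4, -352, -566, -119, 710, -29.4, 5040, 334, 24700],
      "im": [-454, -379, -40.5, -416, 303, -176, 255, -283, 281, -375, 483, 35.8, 258, 605],
      "normalized": false
    },
    {
      "id": "sample_elliptic",
      "class": "elliptic_symmetric",
      "n_points": 64,
      "indices": [2, -2, 3, -3, 4, -4, 5, -5, 6, -6, 7, 1, -1, 0],
      "re": [874, 185, 684, 18.5, 185, -121, -28.6, -381, -119, -638, -12.7, 1650, 285, 23200],
      "im": [479, -162, 292, 60.8, 156, -223, -211, 214, 339, 308, 549, 168, -271, -396],
      "normalized": false
    },
    {
      "id": "sample_asymmetric",
      "class": "asymmetric",
      "n_points": 64,
      "indices": [2, -2, 3, -3, 4, -4, 5, -5, 6, -6, 7, 1, -1, 0],
      "re": [1750, -68.3, 403, -142, 217, -94.4, 26.7, -554, -275, -289, -276, 3000, 377, 25400],
      "im": [-119, -526, 136, -102, 96.8, 2.60, -71.9, -226, 203, -189, 358, 77.4, 108, 813],
      "normalized": false
    }
  ]
}
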