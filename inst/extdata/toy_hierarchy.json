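[
  {
    "name": "brain",
    "parent": null,
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "telencephalon",
    "parent": "brain",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "brainstem",
    "parent": "brain",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "cerebellum",
    "parent": "brain",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "left-cerebral-cortex",
    "parent": "telencephalon",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "left-frontal-lobe",
    "parent": "left-cerebral-cortex",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "left-temporal-lobe",
    "parent": "left-cerebral-cortex",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "left-precentral-gyrus",
    "parent": "left-frontal-lobe",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "left-orbitofrontal-cortex",
    "parent": "left-frontal-lobe",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "left-superior-temporal-gyrus",
    "parent": "left-temporal-lobe",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "left-area-6d1",
    "parent": "left-precentral-gyrus",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "left-area-6d2",
    "parent": "left-precentral-gyrus",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "left-area-fo1",
    "parent": "left-orbitofrontal-cortex",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "left-area-fo2",
    "parent": "left-orbitofrontal-cortex",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "left-area-fo3",
    "parent": "left-orbitofrontal-cortex",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "left-area-te1",
    "parent": "left-superior-temporal-gyrus",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "left-area-te2",
    "parent": "left-superior-temporal-gyrus",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "right-cerebral-cortex",
    "parent": "telencephalon",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "right-frontal-lobe",
    "parent": "right-cerebral-cortex",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "right-temporal-lobe",
    "parent": "right-cerebral-cortex",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "right-precentral-gyrus",
    "parent": "right-frontal-lobe",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "right-orbitofrontal-cortex",
    "parent": "right-frontal-lobe",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "right-superior-temporal-gyrus",
    "parent": "right-temporal-lobe",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "right-area-6d1",
    "parent": "right-precentral-gyrus",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "right-area-6d2",
    "parent": "right-precentral-gyrus",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "right-area-fo1",
    "parent": "right-orbitofrontal-cortex",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "right-area-fo2",
    "parent": "right-orbitofrontal-cortex",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "right-area-fo3",
    "parent": "right-orbitofrontal-cortex",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "right-area-te1",
    "parent": "right-superior-temporal-gyrus",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "right-area-te2",
    "parent": "right-superior-temporal-gyrus",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "mesencephalon",
    "parent": "brainstem",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "pons",
    "parent": "brainstem",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "substantia-nigra",
    "parent": "mesencephalon",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "red-nucleus",
    "parent": "mesencephalon",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "left-cerebellar-cortex",
    "parent": "cerebellum",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "right-cerebellar-cortex",
    "parent": "cerebellum",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "cerebellar-nuclei",
    "parent": "cerebellum",
    "is_elementary": false,
    "map_ref": null
  },
  {
    "name": "left-dentate-nucleus",
    "parent": "cerebellar-nuclei",
    "is_elementary": true,
    "map_ref": null
  },
  {
    "name": "right-dentate-nucleus",
    "parent": "cerebellar-nuclei",
    "is_elementary": true,
    "map_ref": null
  }
]
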