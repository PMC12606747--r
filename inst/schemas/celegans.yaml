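# C. elegans: 5 midline keypoints along the body axis, one part per
# keypoint. No bilateral pairs (flip_partner defaults to self).
species: celegans
center_rule: keypoint_centroid
keypoints:
  - {name: head,   oks_k: 0.1}
  - {name: front,  oks_k: 0.1}
  - {name: middle, oks_k: 0.1}
  - {name: back,   oks_k: 0.1}
  - {name: tail,   oks_k: 0.1}
parts:
  - {name: head,   keypoints: [head]}
  - {name: front,  keypoints: [front]}
  - {name: middle, keypoints: [middle]}
  - {name: back,   keypoints: [back]}
  - {name: tail,   keypoints: [tail]}
skeleton:
  - [head, front]
  - [front, middle]
  - [middle, back]
  - [back, tail]
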