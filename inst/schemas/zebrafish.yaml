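# Zebrafish: 10 keypoints in 5 parts (head / dorsal / ventral / mid-body /
# caudal). The exact keypoint naming of the source annotations is not
# published; this assignment is a documented stand-in and can be overridden
# with a user schema file. Dorsal/ventral flank points swap under a
# horizontal mirror (top-view imaging).
species: zebrafish
center_rule: keypoint_centroid
keypoints:
  - {name: snout,           oks_k: 0.1}
  - {name: head_left,       oks_k: 0.1, flip_partner: head_right}
  - {name: head_right,      oks_k: 0.1, flip_partner: head_left}
  - {name: dorsal_front,    oks_k: 0.1, flip_partner: ventral_front}
  - {name: dorsal_rear,     oks_k: 0.1, flip_partner: ventral_rear}
  - {name: ventral_front,   oks_k: 0.1, flip_partner: dorsal_front}
  - {name: ventral_rear,    oks_k: 0.1, flip_partner: dorsal_rear}
  - {name: mid_body,        oks_k: 0.1}
  - {name: caudal_peduncle, oks_k: 0.1}
  - {name: tail_tip,        oks_k: 0.1}
parts:
  - {name: head,     keypoints: [snout, head_left, head_right]}
  - {name: dorsal,   keypoints: [dorsal_front, dorsal_rear]}
  - {name: ventral,  keypoints: [ventral_front, ventral_rear]}
  - {name: mid_body, keypoints: [mid_body]}
  - {name: caudal,   keypoints: [caudal_peduncle, tail_tip]}
skeleton:
  - [snout, head_left]
  - [snout, head_right]
  - [snout, mid_body]
  - [dorsal_front, dorsal_rear]
  - [ventral_front, ventral_rear]
  - [mid_body, caudal_peduncle]
  - [caudal_peduncle, tail_tip]
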