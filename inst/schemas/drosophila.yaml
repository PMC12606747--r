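# Drosophila: 26 keypoints in 9 parts (each part 1-6 keypoints). The source
# annotation key is only published pictorially; this is a documented
# plausible stand-in: head (proboscis + antennae), eyes, thorax, abdomen,
# two wings, and three leg-pair groups with a joint and a tip per leg.
species: drosophila
center_rule: keypoint_centroid
keypoints:
  - {name: proboscis,            oks_k: 0.1}
  - {name: antenna_left,         oks_k: 0.1, flip_partner: antenna_right}
  - {name: antenna_right,        oks_k: 0.1, flip_partner: antenna_left}
  - {name: eye_left,             oks_k: 0.1, flip_partner: eye_right}
  - {name: eye_right,            oks_k: 0.1, flip_partner: eye_left}
  - {name: notum,                oks_k: 0.1}
  - {name: scutellum,            oks_k: 0.1}
  - {name: abdomen_base,         oks_k: 0.1}
  - {name: abdomen_mid,          oks_k: 0.1}
  - {name: abdomen_tip,          oks_k: 0.1}
  - {name: wing_left_base,       oks_k: 0.1, flip_partner: wing_right_base}
  - {name: wing_left_tip,        oks_k: 0.1, flip_partner: wing_right_tip}
  - {name: wing_right_base,      oks_k: 0.1, flip_partner: wing_left_base}
  - {name: wing_right_tip,       oks_k: 0.1, flip_partner: wing_left_tip}
  - {name: leg_front_left_joint, oks_k: 0.1, flip_partner: leg_front_right_joint}
  - {name: leg_front_left_tip,   oks_k: 0.1, flip_partner: leg_front_right_tip}
  - {name: leg_front_right_joint, oks_k: 0.1, flip_partner: leg_front_left_joint}
  - {name: leg_front_right_tip,  oks_k: 0.1, flip_partner: leg_front_left_tip}
  - {name: leg_mid_left_joint,   oks_k: 0.1, flip_partner: leg_mid_right_joint}
  - {name: leg_mid_left_tip,     oks_k: 0.1, flip_partner: leg_mid_right_tip}
  - {name: leg_mid_right_joint,  oks_k: 0.1, flip_partner: leg_mid_left_joint}
  - {name: leg_mid_right_tip,    oks_k: 0.1, flip_partner: leg_mid_left_tip}
  - {name: leg_hind_left_joint,  oks_k: 0.1, flip_partner: leg_hind_right_joint}
  - {name: leg_hind_left_tip,    oks_k: 0.1, flip_partner: leg_hind_right_tip}
  - {name: leg_hind_right_joint, oks_k: 0.1, flip_partner: leg_hind_left_joint}
  - {name: leg_hind_right_tip,   oks_k: 0.1, flip_partner: leg_hind_left_tip}
parts:
  - {name: head,      keypoints: [proboscis, antenna_left, antenna_right]}
  - {name: eyes,      keypoints: [eye_left, eye_right]}
  - {name: thorax,    keypoints: [notum, scutellum]}
  - {name: abdomen,   keypoints: [abdomen_base, abdomen_mid, abdomen_tip]}
  - {name: wing_left,  keypoints: [wing_left_base, wing_left_tip]}
  - {name: wing_right, keypoints: [wing_right_base, wing_right_tip]}
  - {name: legs_front, keypoints: [leg_front_left_joint, leg_front_left_tip,
                                   leg_front_right_joint, leg_front_right_tip]}
  - {name: legs_mid,   keypoints: [leg_mid_left_joint, leg_mid_left_tip,
                                   leg_mid_right_joint, leg_mid_right_tip]}
  - {name: legs_hind,  keypoints: [leg_hind_left_joint, leg_hind_left_tip,
                                   leg_hind_right_joint, leg_hind_right_tip]}
skeleton:
  - [proboscis, notum]
  - [antenna_left, proboscis]
  - [antenna_right, proboscis]
  - [eye_left, notum]
  - [eye_right, notum]
  - [notum, scutellum]
  - [scutellum, abdomen_base]
  - [abdomen_base, abdomen_mid]
  - [abdomen_mid, abdomen_tip]
  - [wing_left_base, wing_left_tip]
  - [wing_right_base, wing_right_tip]
  - [leg_front_left_joint, leg_front_left_tip]
  - [leg_front_right_joint, leg_front_right_tip]
  - [leg_mid_left_joint, leg_mid_left_tip]
  - [leg_mid_right_joint, leg_mid_right_tip]
  - [leg_hind_left_joint, leg_hind_left_tip]
  - [leg_hind_right_joint, leg_hind_right_tip]
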