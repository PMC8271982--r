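{
  "format": "skeleton-csv",
  "description": "One row per frame per joint of a 15-joint skeleton recording. A file may hold many samples, distinguished by sample_id. Frames are 1-based and consecutive; joint_index follows the canonical numbering (1 head, 2 neck, 3 torso, 4-6 left shoulder/elbow/wrist, 7-9 right shoulder/elbow/wrist, 10-12 left hip/knee/ankle, 13-15 right hip/knee/ankle). Coordinates are in meters in the sensor camera frame (x lateral, y up, z depth).",
  "columns": [
    {"name": "sample_id", "type": "string"},
    {"name": "frame", "type": "integer", "minimum": 1},
    {"name": "joint_index", "type": "integer", "minimum": 1, "maximum": 15},
    {"name": "joint_name", "type": "string"},
    {"name": "x", "type": "number"},
    {"name": "y", "type": "number"},
    {"name": "z", "type": "number"}
  ],
  "companion": {
    "manifest.csv": ["sample_id", "subject", "class", "viewpoint", "seed"]
  }
}
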