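{
  "format": "skelact-config",
  "description": "YAML configuration accepted by loadConfig() and the CLI's --config flag. All keys optional; unknown keys are rejected.",
  "keys": {
    "data_dir": {"type": "string", "default": "data"},
    "model_dir": {"type": "string", "default": "models"},
    "report_dir": {"type": "string", "default": "reports"},
    "ordering": {"type": "string", "default": "B1"},
    "window_length": {"type": "integer", "default": 32},
    "window_stride": {"type": "integer", "default": 1},
    "epochs": {"type": "integer", "default": 200},
    "batch_size": {"type": "integer", "default": 64},
    "lr": {"type": "number", "default": 0.01},
    "runs": {"type": "integer", "default": 20},
    "subjects": {"type": "integer", "default": 32},
    "frames": {"type": "integer", "default": 64},
    "sigma": {"type": "number", "default": 0.01},
    "log_level": {"type": "string", "default": "info"}
  }
}
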