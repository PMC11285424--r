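{
 "": {
  "the": 0.5,
  "a": 0.3,
  "dogs": 0.1,
  "run": 0.1
 },
 "the": {
  "dogs": 0.6,
  "run": 0.4
 },
 "a": {
  "dogs": 0.7,
  "run": 0.3
 },
 "the dogs": {
  "run": 1.0
 }
}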