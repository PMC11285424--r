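{
 "the": [
  0.1,
  0.2,
  0.0
 ],
 "a": [
  0.2,
  0.1,
  0.1
 ],
 "dogs": [
  0.9,
  0.1,
  0.3
 ],
 "run": [
  0.5,
  0.8,
  0.1
 ],
 "cats": [
  0.85,
  0.2,
  0.35
 ]
}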