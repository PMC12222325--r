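# The three published base/novel class splits of the PestDet20 few-shot
# benchmark (20 classes; 15 base, 5 novel per split). These are fixture
# loads: the shuffling seed behind them was never published.
splits:
- id: 1
  all: [15, 76, 24, 39, 14, 67, 16, 95, 25, 3, 66, 0, 101, 99, 37, 70, 26, 50, 48, 21]
  base: [15, 76, 24, 39, 14, 67, 16, 95, 25, 3, 66, 0, 101, 99, 37]
  novel: [70, 26, 50, 48, 21]
- id: 2
  all: [101, 14, 48, 15, 3, 67, 39, 66, 76, 50, 95, 26, 37, 24, 0, 16, 21, 99, 70, 25]
  base: [101, 14, 48, 15, 3, 67, 39, 66, 76, 50, 95, 26, 37, 24, 0]
  novel: [16, 21, 99, 70, 25]
- id: 3
  all: [0, 48, 14, 99, 3, 21, 39, 66, 16, 37, 50, 26, 25, 70, 24, 67, 101, 76, 15, 95]
  base: [0, 48, 14, 99, 3, 21, 39, 66, 16, 37, 50, 26, 25, 70, 24]
  novel: [67, 101, 76, 15, 95]
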