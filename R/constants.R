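## Canonical modality labels and their native sampling rates (Hz).
## THOR and ABD are kept separate at I/O level; their standardized sum ("TA")
## is formed during preprocessing.
CANONICAL_CHANNELS <- c("NP", "THOR", "ABD", "HR", "PPG", "SPO2", "PCO2")

NATIVE_RATES <- c(NP = 200, THOR = 50, ABD = 50, HR = 1, PPG = 100,
                  SPO2 = 2, PCO2 = 2)

CHANNEL_UNITS <- c(NP = "a.u.", THOR = "a.u.", ABD = "a.u.", HR = "bpm",
                   PPG = "a.u.", SPO2 = "%", PCO2 = "mmHg")

## Event vocabulary. Apnea/hypopnea subtypes form the adverse-event class;
## intermittent hypoxia is annotated but never adverse; movement is masked
## from analysis but not adverse.
ADVERSE_KINDS <- c("central_apnea", "obstructive_apnea", "mixed_apnea",
                   "central_hypopnea", "obstructive_hypopnea")
EVENT_KINDS <- c(ADVERSE_KINDS, "hypoxia", "movement")

## Model-input geometry: oscillatory modalities at 5 Hz, slow modalities at
## 1 Hz, over a 30 s window.
FAST_MODALITIES <- c("NP", "TA", "PPG")
SLOW_MODALITIES <- c("HR", "SPO2", "PCO2")
MODALITIES <- c(FAST_MODALITIES, SLOW_MODALITIES)

RANGE_NORM <- list(HR = c(50, 240), SPO2 = c(60, 100), PCO2 = c(30, 70))

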