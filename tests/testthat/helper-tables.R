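# Printed per-fold evaluation tables of the reference study (five case-2
# transfer-learning iterations), used as pure inputs to the summary
# arithmetic. Columns: accuracy %, loss, F1 %, precision %, recall %,
# specificity %. Timing columns are out of scope and omitted.

published_iteration_tables <- list(
  iter1 = list(
    folds = rbind(
      c(92.82, 0.24, 91.75, 92.39, 91.26, 96.11),
      c(93.64, 0.21, 93.11, 92.81, 93.43, 96.75),
      c(92.82, 0.26, 92.15, 92.39, 91.92, 96.19),
      c(92.66, 0.28, 91.49, 91.61, 91.41, 96.08),
      c(93.46, 0.22, 92.52, 93.15, 92.03, 96.56)),
    mean = c(93.08, 0.24, 92.21, 92.47, 92.01, 96.34),
    sd = c(0.44, 0.03, 0.64, 0.58, 0.86, 0.29)),
  iter2 = list(
    folds = rbind(
      c(97.72, 0.07, 97.66, 97.48, 97.84, 98.83),
      c(97.55, 0.11, 97.41, 97.41, 97.41, 98.72),
      c(97.88, 0.06, 97.63, 97.29, 98.01, 98.97),
      c(97.72, 0.09, 97.51, 97.42, 97.59, 98.85),
      c(96.73, 0.11, 96.16, 96.86, 95.66, 98.22)),
    mean = c(97.52, 0.09, 97.27, 97.29, 97.31, 98.72),
    sd = c(0.46, 0.02, 0.63, 0.25, 0.95, 0.29)),
  iter3 = list(
    folds = rbind(
      c(99.02, 0.03, 98.82, 98.74, 98.89, 99.55),
      c(98.21, 0.05, 98.03, 97.79, 98.27, 99.14),
      c(98.53, 0.05, 98.42, 98.54, 98.31, 99.23),
      c(98.53, 0.06, 98.28, 98.29, 98.28, 99.28),
      c(98.69, 0.04, 98.58, 98.68, 98.49, 99.29)),
    mean = c(98.59, 0.05, 98.43, 98.41, 98.45, 99.29),
    sd = c(0.29, 0.01, 0.29, 0.39, 0.26, 0.15)),
  iter4 = list(
    folds = rbind(
      c(98.37, 0.06, 98.29, 98.42, 98.18, 99.14),
      c(98.37, 0.05, 98.13, 98.05, 98.21, 99.18),
      c(98.21, 0.05, 97.98, 97.85, 98.13, 99.15),
      c(99.35, 0.03, 99.29, 99.33, 99.25, 99.64),
      c(98.86, 0.05, 98.66, 98.59, 98.74, 99.46)),
    mean = c(98.63, 0.05, 98.47, 98.45, 98.51, 99.31),
    sd = c(0.47, 0.01, 0.52, 0.57, 0.49, 0.23)),
  iter5 = list(
    folds = rbind(
      c(98.21, 0.06, 97.99, 98.13, 97.88, 99.07),
      c(99.18, 0.04, 99.05, 98.88, 99.23, 99.62),
      c(98.37, 0.05, 98.05, 98.14, 97.98, 99.19),
      c(99.02, 0.03, 98.95, 98.91, 98.98, 99.51),
      c(98.37, 0.05, 98.28, 98.19, 98.38, 99.18)),
    mean = c(98.63, 0.05, 98.46, 98.45, 98.49, 99.31),
    sd = c(0.44, 0.01, 0.51, 0.41, 0.59, 0.24)))
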