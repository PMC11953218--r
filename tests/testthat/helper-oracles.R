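# independent oracle: classical two-factor within-subject ANOVA via aov()
aov_oracle <- function(d) {
  d$subject_id <- factor(d$subject_id)
  d$waveform <- factor(d$waveform)
  d$direction <- factor(d$direction)
  s <- summary(stats::aov(value ~ waveform * direction +
                            Error(subject_id / (waveform * direction)), data = d))
  list(
    F_w = s[["Error: subject_id:waveform"]][[1]]["waveform", "F value"],
    F_d = s[["Error: subject_id:direction"]][[1]]["direction", "F value"],
    F_wd = s[["Error: subject_id:waveform:direction"]][[1]][
      "waveform:direction", "F value"])
}
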