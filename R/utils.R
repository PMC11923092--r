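# coefficient of determination without summary.lm's perfect-fit warning
r_squared <- function(fit) {
  y <- fit$model[[1]]
  1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
}
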