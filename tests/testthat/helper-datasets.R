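# Synthetic dataset constructor with controlled per-image statistics: image
# i has sd and max both strictly increasing in values[i]; values[i] == 0
# gives an all-zero image.
make_synth_dataset <- function(values, labels = rep(0L, length(values))) {
  n <- length(values)
  data <- array(0, dim = c(n, 144, 256))
  for (i in seq_len(n)) {
    if (values[i] > 0) {
      data[i, 1, 1] <- values[i]
      data[i, 2, 1] <- values[i] / 2
    }
  }
  structure(list(data = data, target = as.integer(labels),
                 metadata = data.frame(model = rep("sphere", n),
                                       label = labels, idx = seq_len(n))),
            class = "sans_dataset")
}
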