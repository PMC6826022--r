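# Shared fixtures built in code. The expensive noiseless video simulation and
# its full analysis are computed once per test run and reused.

noiselessVideoSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simBeatingHeartVideo(
        cardiacSimParams(edv = 4, esv = 2, noise_sd = 0, blur_sigma = 0,
                         seed = 11))
    cache
  }
})

noiselessHeartSummary <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- summarizeHeart(noiselessVideoSim()$video)
    cache
  }
})

# binary-valued intensity frame with one or more discs on a dark background
discFrame <- function(shape, centers, radii, fg = 0.9, bg = 0.1) {
  img <- matrix(bg, shape[1], shape[2])
  for (i in seq_along(radii)) {
    d2 <- outer((seq_len(shape[1]) - centers[[i]][1])^2,
                (seq_len(shape[2]) - centers[[i]][2])^2, "+")
    img[d2 <= radii[i]^2] <- fg
  }
  img
}
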