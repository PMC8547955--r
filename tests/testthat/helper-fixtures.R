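# fixtures shared across test files; everything is built in code

# uniform two-channel image with optional per-channel overrides
flatImage <- function(pmrlc = 100, phalloidin = 150, shape = c(64L, 64L),
                      pixelSize = 0.2, masks = list()) {
    new("FollicleImage",
        channels = list(pmrlc = matrix(pmrlc, shape[1], shape[2]),
                        phalloidin = matrix(phalloidin, shape[1], shape[2])),
        pixelSize = pixelSize, masks = masks)
}

discMask <- function(shape, center, radius) {
    rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
    cols <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
    (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

# three horizontal lines crossing the first default membrane segment
defaultMembraneLines <- function() {
    list(rbind(c(100, 40), c(100, 95)),
         rbind(c(140, 40), c(140, 95)),
         rbind(c(180, 40), c(180, 95)))
}

wtSample   <- function() twoLayerSample(eShallow = 24.2, eDeep = 10.1)
nullSample <- function() twoLayerSample(eShallow = 26.5, eDeep = 25.9)
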