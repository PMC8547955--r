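#' @importFrom stats aov dist mad median optimize rgeom rnorm rpois runif sd
#'   t.test uniroot TukeyHSD
#' @importFrom utils read.csv write.csv packageVersion
NULL
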