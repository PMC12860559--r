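#' Published class-frequency distributions of lettuce leaf traits
#'
#' Class-frequency percentages (classes 1..10) for 16 qualitative leaf
#' traits scored on a 268-accession lettuce core collection in the 2020
#' and 2021 autumn seasons, as published with the collection, together
#' with the published Shannon-Wiener index of each trait-year row. These
#' are the worked inputs for [shannon_index()]: recomputing H' from the
#' percentages reproduces the published column, and the published
#' trait-diversity range (0.40-2.15 nats) is the min/max over the 32
#' rows.
#'
#' @return data.frame with columns `trait`, `year`, `c1`..`c10`
#'   (percent per class) and `h_published`.
#' @export
lettuce_trait_frequencies <- function() {
  tx <- "
trait|year|c1|c2|c3|c4|c5|c6|c7|c8|c9|c10|h_published
Shape of leaf tip|2020|10.99|24.61|64.40|0|0|0|0|0|0|0|0.87
Leaf thickness|2020|26.18|45.03|28.80|0|0|0|0|0|0|0|1.07
Leaf attitude|2020|25.79|0|63.16|11.05|0|0|0|0|0|0|0.88
Undulation of leaf margin|2020|0|0|61.78|25.13|13.09|0|0|0|0|0|0.91
Leaf shape|2020|9.42|16.75|5.76|13.61|15.18|2.62|14.14|10.99|1.57|9.95|2.15
Leaf blistering|2020|36.13|0|34.03|0|15.18|0|14.66|0|0|0|1.30
Plant width|2020|6.81|0|13.61|0|37.70|0|28.27|0|13.61|0|1.45
Leaf blade incision in apical margin|2020|36.65|0|0|0|0|0|0|0|63.35|0|0.66
Glossiness of leaf|2020|27.75|35.08|36.65|0.52|0|0|0|0|0|0|1.12
Outer leaf color|2020|42.93|22.51|15.71|18.85|0|0|0|0|0|0|1.30
Leaf venation|2020|50.79|49.21|0|0|0|0|0|0|0|0|0.69
Outer leaf color intensity|2020|0|0|29.32|0|36.65|0|34.03|0|0|0|1.09
Leaf anthocyanin coloration|2020|66.49|0|0|0|0|0|0|0|33.51|0|0.64
Head formation|2020|58.64|17.80|23.56|0|0|0|0|0|0|0|0.96
Leaf texture|2020|85.86|14.14|0|0|0|0|0|0|0|0|0.41
Leaf lobes of margin|2020|85.86|7.33|6.81|0|0|0|0|0|0|0|0.51
Shape of leaf tip|2021|12.62|13.59|73.79|0|0|0|0|0|0|0|0.76
Leaf thickness|2021|36.89|29.61|33.50|0|0|0|0|0|0|0|1.09
Leaf attitude|2021|21.84|0|27.18|50.97|0|0|0|0|0|0|1.03
Undulation of leaf margin|2021|0|0|75.73|17.48|6.80|0|0|0|0|0|0.70
Leaf shape|2021|14.08|10.68|6.31|17.96|14.08|4.85|5.34|12.62|0|14.08|2.11
Leaf blistering|2021|18.93|0|33.98|0|22.82|0|14.08|0|10.19|0|1.53
Plant width|2021|7.28|0|19.90|0|41.75|0|24.27|0|6.80|0|1.40
Leaf blade incision in apical margin|2021|32.04|0|0|0|0|0|0|0|67.96|0|0.63
Glossiness of leaf|2021|28.64|34.47|36.89|0|0|0|0|0|0|0|1.09
Outer leaf color|2021|60.98|13.66|8.78|16.59|0|0|0|0|0|0|1.09
Leaf venation|2021|45.63|54.37|0|0|0|0|0|0|0|0|0.69
Outer leaf color intensity|2021|0|0|32.68|0|45.37|0|21.95|0|0|0|1.06
Leaf anthocyanin coloration|2021|69.42|0|0|0|0|0|0|0|30.58|0|0.62
Head formation|2021|55.83|11.17|32.52|0|0.49|0|0|0|0|0|0.96
Leaf texture|2021|69.42|30.58|0|0|0|0|0|0|0|0|0.62
Leaf lobes of margin|2021|89.32|8.25|2.43|0|0|0|0|0|0|0|0.40"
  utils::read.delim(text = tx, sep = "|", strip.white = TRUE,
                    stringsAsFactors = FALSE)
}
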