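#' Health states of the cardiovascular disease model
#'
#' The model distinguishes nine states: an event-free state, five first-event
#' disease states (stroke, heart failure, myocardial infarction, angina,
#' peripheral vascular disease), and death. MI and angina are split into a
#' one-cycle acute "tunnel" state and a chronic post-event state, so that the
#' acute event year can carry its own utility and cost.
#'
#' @return Character vector of the nine state labels, in canonical order.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("EventFree", "Stroke", "HF", "AcuteMI", "PostMI",
    "AcuteAngina", "PostAngina", "PVD", "Dead")
}

# first-event types considered from the event-free state
model_events <- function() c("stroke", "hf", "mi", "angina", "pvd")

#' Treatment strategy labels
#'
#' The six arms compared: the four-component polypill and its individual
#' components given as monotherapy (valsartan and enalapril being the two
#' alternative renin-angiotensin blockers).
#'
#' @return Character vector of the six strategy labels.
#' @export
strategy_labels <- function() {
  c("polypill", "atorvastatin", "hydrochlorothiazide",
    "aspirin", "enalapril", "valsartan")
}
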