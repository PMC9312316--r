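Package: infodemiR
Title: Neural Topic and Informed Sentiment Analysis for Social-Media
    Disease Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for infodemiology: mining disease-outbreak signal from
    tweet-like text streams. Implements a semi-supervised neural topic model
    (a variational autoencoder over bag-of-words counts, optionally fused
    with contextual document embeddings, with a product-of-experts decoder
    and a classification head on the latent space), an informed neural
    network sentiment classifier (an LSTM data branch regularised by a
    lexicon-and-rules prior-knowledge branch), the Semantic Brand Score
    (prevalence, diversity and connectivity of a concept in a word
    co-occurrence network), topic-quality metrics (NPMI coherence,
    embedding coherence, inverted rank-biased overlap) and classification
    metrics, plus spatio-temporal slicing of tweet streams into weekly and
    per-location volume, sentiment-ratio, topic-evolution and brand-score
    series. Deterministic synthetic-corpus generators emulate the
    statistical structure each method assumes, so the whole pipeline runs
    and is tested without any external data download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    caret,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
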