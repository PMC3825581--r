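experiment_id	label
Smith 2001: object identity working memory	cognition
Jones 2003: object location working memory	cognition
Lee 2005: spatial attention	attention
Chen 2007: shape recognition	perception
Weber 2009: verbal rehearsal	cognition
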