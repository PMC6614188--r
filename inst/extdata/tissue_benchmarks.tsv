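tissue	n_train_normal	n_test_normal	n_test_cancer	precision	recall	specificity	accuracy	auc
breast	89	110	982	0.975	0.965	0.782	0.947	0.903
liver	115	48	295	0.986	0.939	0.917	0.936	0.973
lung	313	59	503	0.987	0.907	0.898	0.906	0.960
prostate	106	48	426	0.949	0.742	0.646	0.732	0.734
stomach	192	33	380	0.943	0.966	0.333	0.915	0.547
thyroid	318	53	441	0.974	0.925	0.792	0.911	0.893
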