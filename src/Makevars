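# GLPK ships with the R installation's prefix (conda layout: $R_HOME/../..)
GLPK_PREFIX = $(R_HOME)/../..
PKG_CPPFLAGS = -I$(GLPK_PREFIX)/include
PKG_LIBS = -L$(GLPK_PREFIX)/lib -lglpk -Wl,-rpath,$(GLPK_PREFIX)/lib
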